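cfg <- extraction_config()

test_that("mention finder matches surface variants with word boundaries and negates fever words", {
  expect_equal(nrow(find_fev1_mentions("", cfg)), 0)
  expect_equal(nrow(find_fev1_mentions("Pt had fever 103.2 overnight", cfg)), 0)
  expect_equal(nrow(find_fev1_mentions("feverish and FEVERS noted", cfg)), 0)
  expect_equal(nrow(find_fev1_mentions("FEV10 recorded", cfg)), 0)
  expect_equal(nrow(find_fev1_mentions("XFEV1 2.0", cfg)), 0)

  m <- find_fev1_mentions("fev_1 was 45% predicted; FEV-1 1.2", cfg)
  expect_equal(m$start, c(0L, 25L))
  expect_equal(m$end, c(5L, 30L))
  expect_equal(m$surface, c("fev_1", "FEV-1"))

  # surface always equals the 0-based half-open slice of the text
  text <- "spirometry: FEV 1 of 58% (FEV1 1.4 L)"
  m <- find_fev1_mentions(text, cfg)
  expect_equal(m$surface, substring(text, m$start + 1, m$end))

  # variant list is configurable: dropping "FEV 1" removes the space form
  narrow <- extraction_config(pattern_variants = c("FEV1", "FEV-1", "FEV_1"))
  expect_equal(nrow(find_fev1_mentions("FEV 1 of 58%", narrow)), 0)
})

test_that("window scan returns the leftmost numeric token within the forward window", {
  text <- "FEV1 1.85 L (62% predicted)"
  m <- find_fev1_mentions(text, cfg)[1, ]
  hit <- scan_window_for_value(text, m, cfg)
  expect_equal(hit$raw_token, "1.85")
  expect_equal(hit$value_start, 5L)

  expect_null(scan_window_for_value(
    "FEV1 improved since last visit.",
    find_fev1_mentions("FEV1 improved since last visit.", cfg)[1, ], cfg
  ))

  # definitional boundary: first digit exactly window_chars past mention end
  at_edge <- paste0("FEV1 ", strrep("x", cfg$window_chars - 1), "5")
  m <- find_fev1_mentions(at_edge, cfg)[1, ]
  hit <- scan_window_for_value(at_edge, m, cfg)
  expect_equal(hit$raw_token, "5")
  expect_equal(hit$value_start - m$end, cfg$window_chars)
  past_edge <- paste0("FEV1 ", strrep("x", cfg$window_chars), "5")
  expect_null(scan_window_for_value(past_edge, find_fev1_mentions(past_edge, cfg)[1, ], cfg))
})

test_that("ratio guard and date-like skip behave as configured", {
  text <- "FEV1/FVC 0.55"
  m <- find_fev1_mentions(text, cfg)[1, ]
  expect_null(scan_window_for_value(text, m, cfg))
  no_guard <- extraction_config(exclude_ratio_context = FALSE)
  expect_equal(scan_window_for_value(text, m, no_guard)$raw_token, "0.55")

  text <- "FEV1 on 12/04 was 1.85"
  m <- find_fev1_mentions(text, cfg)[1, ]
  expect_equal(scan_window_for_value(text, m, cfg)$raw_token, "1.85")
  no_skip <- extraction_config(skip_datelike = FALSE)
  expect_equal(scan_window_for_value(text, m, no_skip)$raw_token, "12")

  # every component of a full date is passed over
  text <- "FEV1 12/04/2019 1.20 L"
  m <- find_fev1_mentions(text, cfg)[1, ]
  expect_equal(scan_window_for_value(text, m, cfg)$raw_token, "1.20")
})

test_that("value validation applies unit hints and plausibility ranges", {
  expect_equal(validate_value("1.85", cfg), list(value = 1.85, unit_guess = "liters"))
  expect_equal(validate_value("58%", cfg), list(value = 58, unit_guess = "percent_predicted"))
  expect_equal(validate_value("58", cfg)$unit_guess, "percent_predicted")
  expect_null(validate_value("350", cfg))
  expect_null(validate_value("9", cfg)) # between the two ranges
  expect_null(validate_value("5%", cfg)) # % pinned but implausible as percent
  expect_null(validate_value("not-a-number", cfg))
})

test_that("extract_note takes the first valid value and flags multiple mentions", {
  note <- list(
    note_id = "n1", patient_id = "p1",
    text = "Spirometry today: FEV1 1.10 L (38% pred), FVC 2.9"
  )
  out <- extract_note(note, cfg)
  expect_equal(nrow(out), 1)
  expect_equal(out$value, 1.10)
  expect_equal(out$unit_guess, "liters")
  expect_false(out$multi_mention)

  note$text <- "FEV1 2.4 today, previously FEV1 2.1"
  out <- extract_note(note, cfg)
  expect_equal(nrow(out), 1)
  expect_equal(out$value, 2.4)
  expect_true(out$multi_mention)

  all_out <- extract_note(note, extraction_config(emit_all_mentions = TRUE))
  expect_equal(all_out$value, c(2.4, 2.1))

  note$text <- ""
  expect_equal(nrow(extract_note(note, cfg)), 0)

  # a guarded ratio mention is abandoned, the next mention still yields
  note$text <- "FEV1/FVC 0.55; FEV1 1.85 L"
  out <- extract_note(note, cfg)
  expect_equal(out$value, 1.85)
  expect_true(out$multi_mention)
})

test_that("no extraction ever comes from notes whose only FEV-prefixed tokens are fever words", {
  texts <- c(
    "fever of 103.2", "Feverish, temp 101", "recurrent fevers 99.8",
    "FEVER 102 overnight", "low-grade fever 100.4 resolving"
  )
  for (t in texts) {
    expect_equal(nrow(extract_note(list(note_id = "x", patient_id = "y", text = t), cfg)), 0)
  }
})

test_that("recorded offsets re-slice the note text to the matched strings", {
  corpus <- generate_corpus(sim_config(n_notes = 150, seed = 3))
  ext <- extract_corpus(corpus$notes, extraction_config(emit_all_mentions = TRUE))
  expect_gt(nrow(ext), 0)
  texts <- corpus$notes$text[match(ext$note_id, corpus$notes$note_id)]
  for (i in seq_len(nrow(ext))) {
    mention <- substring(texts[i], ext$mention_start[i] + 1, ext$mention_end[i])
    expect_true(tolower(gsub("[-_ ]", "", mention)) == "fev1")
    expect_true(ext$value_start[i] >= ext$mention_end[i])
    expect_lte(ext$value_start[i] - ext$mention_end[i], 20)
    tail_chr <- substring(texts[i], ext$value_start[i] + 1, ext$value_start[i] + 1)
    expect_match(tail_chr, "[0-9]")
  }
})

test_that("window scanner agrees with the brute-force character-walk oracle", {
  set.seed(401)
  tested <- 0L
  for (rep in 1:600) {
    text <- random_scan_string()
    mentions <- find_fev1_mentions(text, cfg)
    for (i in seq_len(nrow(mentions))) {
      got <- scan_window_for_value(text, mentions[i, ], cfg)
      want <- oracle_scan(text, mentions$end[i])
      expect_identical(got$raw_token, want$raw_token, label = sprintf("token for %s", text))
      expect_identical(
        as.integer(got$value_start), as.integer(want$value_start),
        label = sprintf("offset for %s", text)
      )
      tested <- tested + 1L
    }
  }
  expect_gt(tested, 200)
})

test_that("extract_corpus validates candidate ids and is byte-deterministic", {
  corpus <- generate_corpus(sim_config(n_notes = 100, seed = 5))
  expect_equal(nrow(extract_corpus(corpus$notes, cfg, candidate_ids = character())), 0)
  expect_error(
    extract_corpus(corpus$notes, cfg, candidate_ids = "no-such-note"),
    class = "spirotext_validation_error"
  )

  ext1 <- extract_corpus(corpus$notes, cfg)
  ext2 <- extract_corpus(corpus$notes, cfg)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_extractions(ext1, p1)
  write_extractions(ext2, p2)
  expect_identical(readLines(p1), readLines(p2))
})
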