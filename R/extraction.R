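# Second pass: locate FEV1 surface-pattern mentions, scan a bounded forward
# character window for the first numeric token, validate plausibility, and
# emit extracted values. All offsets in this module are 0-based, half-open
# — one stated convention throughout prevents off-by-one drift between the
# mention finder, the window scanner and the recorded output.

#' Extraction configuration
#'
#' Parameters of the pattern pass.
#'
#' @param window_chars forward scan window in characters after the mention
#'   (default 20): the first numeric token whose first character lies at
#'   most this far past the mention end is taken.
#' @param pattern_variants surface forms recognized as an FEV1 mention.
#'   `"FEV 1"` (space separator) is included beyond the classic
#'   `FEV1`/`FEV-1`/`FEV_1` trio as a common transcription variant; remove
#'   it here to disable.
#' @param liters_range closed plausibility interval for values read as
#'   liters (default `c(0.2, 8)`).
#' @param percent_range closed plausibility interval for values read as
#'   percent of predicted (default `c(10, 160)`).
#' @param exclude_ratio_context if `TRUE` (default) a mention is abandoned
#'   when the text between the mention and the numeric token contains
#'   `"FVC"`, so the FEV1/FVC ratio is never captured as an FEV1 value.
#' @param skip_datelike if `TRUE` (default) a numeric token immediately
#'   followed by `"/"` and a digit (date-like, e.g. `12/04`) is skipped and
#'   scanning continues.
#' @param emit_all_mentions if `FALSE` (default) at most one value — the
#'   first mention yielding a valid value — is emitted per note.
#' @return object of class `extraction_config`.
#' @export
extraction_config <- function(window_chars = 20L,
                              pattern_variants = c("FEV1", "FEV-1", "FEV_1", "FEV 1"),
                              liters_range = c(0.2, 8.0),
                              percent_range = c(10.0, 160.0),
                              exclude_ratio_context = TRUE,
                              skip_datelike = TRUE,
                              emit_all_mentions = FALSE) {
  window_chars <- as.integer(window_chars)
  if (is.na(window_chars) || window_chars < 1L) {
    stop_validation("window_chars must be a positive integer")
  }
  if (!length(pattern_variants) || !all(nzchar(pattern_variants))) {
    stop_validation("pattern_variants must be a nonempty list of nonempty strings")
  }
  for (rng in list(liters_range, percent_range)) {
    if (length(rng) != 2L || !all(is.finite(rng)) || rng[1] >= rng[2]) {
      stop_validation("ranges must be finite intervals with lower < upper")
    }
  }
  structure(
    list(
      window_chars = window_chars,
      pattern_variants = pattern_variants,
      liters_range = as.numeric(liters_range),
      percent_range = as.numeric(percent_range),
      exclude_ratio_context = isTRUE(exclude_ratio_context),
      skip_datelike = isTRUE(skip_datelike),
      emit_all_mentions = isTRUE(emit_all_mentions)
    ),
    class = "extraction_config"
  )
}

regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

mention_pattern <- function(config) {
  # Longest variants first so alternation picks the maximal surface form at
  # each position. Both boundaries are non-alphanumeric lookarounds: the
  # trailing one rejects "FEV10"; the leading one rejects "XFEV1", which is
  # also required for the candidate pass to be complete (the keyword
  # tokenizer would fold "XFEV1" into a token that is not fev-prefixed).
  variants <- config$pattern_variants[order(-nchar(config$pattern_variants))]
  sprintf(
    "(?i)(?<![[:alnum:]])(?:%s)(?![[:alnum:]])",
    paste(regex_escape(variants), collapse = "|")
  )
}

#' Find FEV1 mentions in note text
#'
#' Case-insensitive matches of the configured surface variants, bounded on
#' both sides by non-alphanumeric characters. The boundary requirement is
#' the negation rule: `"fever"`, `"feverish"`, `"fevers"` can never match
#' because letters continue after `"fev"`, and none of them contain a
#' variant as a standalone token.
#'
#' @param text a character scalar (may be empty).
#' @param config an [extraction_config()].
#' @return data.frame with 0-based half-open offsets `start`, `end` and the
#'   matched `surface`, left-to-right, non-overlapping.
#' @export
#' @examples
#' find_fev1_mentions("fev_1 was 45% predicted; FEV-1 1.2", extraction_config())
find_fev1_mentions <- function(text, config = extraction_config()) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(
    start = integer(), end = integer(), surface = character(),
    stringsAsFactors = FALSE
  )
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr(mention_pattern(config), text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  len <- attr(m, "match.length")
  data.frame(
    start = as.integer(m) - 1L,
    end = as.integer(m) - 1L + len,
    surface = substring(text, m, m + len - 1L),
    stringsAsFactors = FALSE
  )
}

# Numeric token grammar: one or more digits, optionally one decimal point
# with trailing digits, optionally an immediately following "%" (kept as a
# unit hint). Comma-grouped numbers are deliberately not numeric: FEV1 is
# never reported with thousands separators.
NUMERIC_TOKEN_RE <- "[0-9]+(\\.[0-9]+)?%?"

#' Scan the forward window after a mention for the first numeric value
#'
#' Returns the leftmost numeric token whose first character lies within
#' `window_chars` characters of the mention end (the token itself may run
#' past the window). Date-like tokens — followed by `/` + digit, or
#' preceded by `/`, so every component of `12/04/2019` is passed over —
#' are skipped when configured; if the text between the mention and the
#' token contains `"FVC"` and the ratio guard is on, the mention yields
#' nothing.
#'
#' @param text the note text.
#' @param mention a list or one-row data.frame with 0-based `end` offset
#'   (as produced by [find_fev1_mentions()]).
#' @param config an [extraction_config()].
#' @return `NULL`, or a list with `raw_token` and 0-based `value_start`.
#' @export
#' @examples
#' m <- find_fev1_mentions("FEV1 1.85 L (62% predicted)", extraction_config())
#' scan_window_for_value("FEV1 1.85 L (62% predicted)", m[1, ], extraction_config())
scan_window_for_value <- function(text, mention, config = extraction_config()) {
  mend <- as.integer(mention$end)
  tail_text <- slice0(text, mend, nchar(text))
  if (!nzchar(tail_text)) return(NULL)
  toks <- gregexpr(NUMERIC_TOKEN_RE, tail_text, perl = TRUE)[[1]]
  if (toks[1] == -1L) return(NULL)
  lens <- attr(toks, "match.length")
  for (i in seq_along(toks)) {
    rel0 <- as.integer(toks[i]) - 1L # 0-based offset of token within window
    if (rel0 > config$window_chars) return(NULL)
    tok_end1 <- as.integer(toks[i]) + lens[i] - 1L # 1-based inclusive
    if (config$skip_datelike) {
      after <- substr(tail_text, tok_end1 + 1L, tok_end1 + 2L)
      before <- if (rel0 > 0L) substr(tail_text, rel0, rel0) else ""
      if (grepl("^/[0-9]", after) || before == "/") next
    }
    between <- substr(tail_text, 1L, rel0)
    if (config$exclude_ratio_context && grepl("fvc", between, ignore.case = TRUE)) {
      return(NULL)
    }
    return(list(
      raw_token = substr(tail_text, as.integer(toks[i]), tok_end1),
      value_start = mend + rel0
    ))
  }
  NULL
}

#' Validate a raw numeric token against the plausibility ranges
#'
#' A trailing `%` pins the unit to percent-predicted. A bare number is read
#' as liters when it falls in the liters range, as percent-predicted when it
#' falls only in the percent range, and is rejected when in neither —
#' implausible values (ages, dates, years) never survive.
#'
#' @param raw_token token returned by [scan_window_for_value()].
#' @param config an [extraction_config()].
#' @return `NULL` on rejection, else a list with numeric `value` and
#'   `unit_guess` (`"liters"` or `"percent_predicted"`).
#' @export
#' @examples
#' validate_value("1.85", extraction_config()) # liters
#' validate_value("58%", extraction_config()) # percent_predicted
#' validate_value("350", extraction_config()) # NULL: implausible
validate_value <- function(raw_token, config = extraction_config()) {
  if (!is.character(raw_token) || length(raw_token) != 1L) return(NULL)
  is_pct <- endsWith(raw_token, "%")
  value <- suppressWarnings(as.numeric(sub("%$", "", raw_token)))
  if (is.na(value) || !is.finite(value)) return(NULL)
  in_l <- value >= config$liters_range[1] && value <= config$liters_range[2]
  in_p <- value >= config$percent_range[1] && value <= config$percent_range[2]
  if (is_pct) {
    if (in_p) list(value = value, unit_guess = "percent_predicted") else NULL
  } else if (in_l) {
    list(value = value, unit_guess = "liters")
  } else if (in_p) {
    list(value = value, unit_guess = "percent_predicted")
  } else {
    NULL
  }
}

empty_extractions <- function() {
  data.frame(
    note_id = character(), patient_id = character(), value = numeric(),
    unit_guess = character(), mention_start = integer(),
    mention_end = integer(), value_start = integer(),
    window_text = character(), multi_mention = logical(),
    stringsAsFactors = FALSE
  )
}

#' Extract FEV1 values from a single note
#'
#' Composes mention finding, window scanning and validation. With the
#' default `emit_all_mentions = FALSE` at most one record is returned: the
#' first mention (document order) yielding a valid value. `multi_mention`
#' is `TRUE` whenever the note contained more than one mention, regardless
#' of how many validated — flagging the case where the value chosen by the
#' first-value rule may refer to an earlier study.
#'
#' @param note a list or one-row data.frame with `note_id`, `patient_id`,
#'   `text`.
#' @param config an [extraction_config()].
#' @return data.frame of extraction records (possibly zero rows).
#' @export
extract_note <- function(note, config = extraction_config()) {
  text <- as.character(note$text)
  if (is.na(text)) text <- ""
  mentions <- find_fev1_mentions(text, config)
  if (!nrow(mentions)) return(empty_extractions())
  multi <- nrow(mentions) > 1L
  rows <- list()
  for (i in seq_len(nrow(mentions))) {
    hit <- scan_window_for_value(text, mentions[i, ], config)
    if (is.null(hit)) next
    val <- validate_value(hit$raw_token, config)
    if (is.null(val)) next
    rows[[length(rows) + 1L]] <- data.frame(
      note_id = as.character(note$note_id),
      patient_id = as.character(note$patient_id),
      value = val$value,
      unit_guess = val$unit_guess,
      mention_start = mentions$start[i],
      mention_end = mentions$end[i],
      value_start = hit$value_start,
      window_text = slice0(
        text, mentions$end[i],
        min(nchar(text), mentions$end[i] + config$window_chars)
      ),
      multi_mention = multi,
      stringsAsFactors = FALSE
    )
    if (!config$emit_all_mentions) break
  }
  if (!length(rows)) return(empty_extractions())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract FEV1 values over a corpus
#'
#' Batch driver: applies [extract_note()] to each note in input order,
#' optionally restricted to the candidate ids from the keyword pass. The
#' candidate filter changes cost, never results: the candidate pass is
#' complete for every note the pattern pass can extract from.
#'
#' @param notes data.frame of notes.
#' @param config an [extraction_config()].
#' @param candidate_ids optional character vector of note ids (e.g. from
#'   [find_candidates()]); ids absent from the corpus are an integrity
#'   error.
#' @return data.frame of extraction records, corpus order preserved.
#' @export
extract_corpus <- function(notes, config = extraction_config(), candidate_ids = NULL) {
  if (!is.null(candidate_ids)) {
    stray <- setdiff(candidate_ids, notes$note_id)
    if (length(stray)) {
      stop_validation("candidate id not in corpus: '", stray[1], "'")
    }
    keep <- notes$note_id %in% candidate_ids
  } else {
    keep <- rep(TRUE, nrow(notes))
  }
  idx <- which(keep)
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    rows[[k]] <- extract_note(notes[idx[k], ], config)
    if (k %% 10000L == 0L) {
      message("processed ", k, "/", length(idx), " candidate notes")
    }
  }
  rows <- rows[vapply(rows, nrow, integer(1)) > 0L]
  if (!length(rows)) return(empty_extractions())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
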