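write_jsonl_note <- function(note_id = "n1", patient_id = "p1",
                             datetime = "2005-01-01T08:00:00",
                             text = "FEV1 1.85 L", drop = NULL) {
  obj <- list(
    note_id = note_id, patient_id = patient_id,
    note_datetime = datetime, text = text
  )
  obj[setdiff(names(obj), drop)]
  jsonlite::toJSON(obj[setdiff(names(obj), drop)], auto_unbox = TRUE)
}

test_that("read_notes parses JSONL corpora in file order and rejects malformed records", {
  path <- withr::local_tempfile(fileext = ".jsonl")

  writeLines(character(), path)
  expect_equal(nrow(read_notes(path)), 0)

  writeLines(c(
    write_jsonl_note("a", text = "first"),
    write_jsonl_note("b", text = "second"),
    write_jsonl_note("c", text = "third")
  ), path)
  notes <- read_notes(path)
  expect_equal(notes$note_id, c("a", "b", "c"))
  expect_equal(notes$text, c("first", "second", "third"))

  writeLines(c(
    write_jsonl_note("a"),
    write_jsonl_note("b", drop = "note_id"),
    write_jsonl_note("c")
  ), path)
  expect_error(read_notes(path), "record 2", class = "spirotext_validation_error")

  writeLines(c(write_jsonl_note("dup"), write_jsonl_note("dup")), path)
  expect_error(read_notes(path), "duplicate note_id", class = "spirotext_validation_error")

  expect_error(read_notes(tempfile()), class = "spirotext_io_error")
})

test_that("read_notes reads the CSV dialect and validates timestamps", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("note_id,patient_id,note_datetime,text", path)
  expect_equal(nrow(read_notes(path, format = "csv")), 0)

  notes <- make_notes(c("a, quoted \"text\"", "line1\nline2"),
    datetime = c("2005-01-01", "2010-03-04T09:30:00")
  )
  write_notes(notes, path, format = "csv")
  back <- read_notes(path, format = "csv")
  expect_identical(back$text, notes$text)

  writeLines(c("note_id,patient_id,text", "a,b,c"), path)
  expect_error(read_notes(path, format = "csv"), "note_datetime",
    class = "spirotext_validation_error"
  )

  writeLines(c(
    "note_id,patient_id,note_datetime,text",
    "a,b,not-a-date,c"
  ), path)
  expect_error(read_notes(path, format = "csv"), "note_datetime")
})

test_that("notes round-trip through JSONL including embedded newlines and quotes", {
  notes <- make_notes(c("FEV1 2.1 L\nnext line", "he said \"fev\""))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_notes(notes, path)
  expect_identical(read_notes(path), notes)
})

test_that("invalid UTF-8 is a hard failure in strict mode and replaced in lenient mode", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  line <- charToRaw(as.character(write_jsonl_note("a", text = "degXrees")))
  line[which(line == charToRaw("X"))] <- as.raw(0xb0) # bare latin-1 byte
  con <- file(path, "wb")
  writeBin(c(line, charToRaw("\n")), con)
  close(con)
  expect_error(read_notes(path, strict = TRUE), "UTF-8",
    class = "spirotext_validation_error"
  )
  notes <- read_notes(path, strict = FALSE)
  expect_match(notes$text, "deg.rees")
})

test_that("read_structured permits missing values but rejects implausible ones", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,measure_datetime,fev1_value",
    "p1,2005-01-01,1.85",
    "p2,2005-01-02,"
  ), path)
  recs <- read_structured(path)
  expect_equal(nrow(recs), 2)
  expect_equal(recs$fev1_value, c(1.85, NA))

  writeLines(c(
    "patient_id,measure_datetime,fev1_value",
    "p1,2005-01-01,-2"
  ), path)
  expect_error(read_structured(path), "finite and > 0",
    class = "spirotext_validation_error"
  )

  writeLines(c(
    "patient_id,measure_datetime,fev1_value",
    "p1,2005-01-01,abc"
  ), path)
  expect_error(read_structured(path), "unparseable")
})

test_that("read_reference enforces the has_value/reference_value invariant", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("note_id,has_value,reference_value", path)
  expect_equal(nrow(read_reference(path)), 0)

  writeLines(c(
    "note_id,has_value,reference_value",
    "n1,true,1.85",
    "n2,false,"
  ), path)
  refs <- read_reference(path)
  expect_equal(refs$has_value, c(TRUE, FALSE))
  expect_equal(refs$reference_value, c(1.85, NA))

  writeLines(c(
    "note_id,has_value,reference_value",
    "n1,true,"
  ), path)
  expect_error(read_reference(path), "record 1", class = "spirotext_validation_error")

  writeLines(c(
    "note_id,has_value,reference_value",
    "n1,false,2.0"
  ), path)
  expect_error(read_reference(path), "has_value is false")
})

test_that("extraction records round-trip losslessly with clean decimal formatting", {
  notes <- make_notes(c(
    "FEV1 1.85 L today", "FEV-1: 58% predicted", "fev_1 2.40",
    "FEV 1 of 72%", "FEV1 0.95 L and FEV1 1.10 L"
  ))
  ext <- extract_corpus(notes, extraction_config(emit_all_mentions = TRUE))
  expect_gte(nrow(ext), 5)

  path <- withr::local_tempfile(fileext = ".csv")
  write_extractions(ext, path)
  expect_identical(read_extractions(path), ext)

  raw <- readLines(path)
  expect_true(any(grepl("\"1.85\"", raw, fixed = TRUE)))
  expect_false(any(grepl("1.8500000", raw)))

  write_extractions(ext[0, ], path)
  expect_equal(length(readLines(path)), 1) # header only
  expect_equal(nrow(read_extractions(path)), 0)
})
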