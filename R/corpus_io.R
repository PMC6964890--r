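# Readers and writers for every tabular format the pipeline touches:
# note corpora (JSONL or CSV), structured PFT measurement tables, reference
# annotations, and extraction output. All readers are strict by default:
# malformed records raise typed errors naming the offending record rather
# than being dropped silently.

NOTE_FIELDS <- c("note_id", "patient_id", "note_datetime", "text")

EXTRACTION_COLUMNS <- c(
  "note_id", "patient_id", "value", "unit_guess",
  "mention_start", "mention_end", "value_start", "window_text", "multi_mention"
)

read_text_lines <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop_io("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  bad <- !validUTF8(lines)
  if (any(bad)) {
    if (strict) {
      stop_validation("invalid UTF-8 on line ", which(bad)[1], " of ", path)
    }
    lines[bad] <- iconv(lines[bad], from = "UTF-8", to = "UTF-8", sub = "�")
  }
  lines
}

read_csv_strict <- function(path, strict = TRUE) {
  lines <- read_text_lines(path, strict = strict)
  if (!length(lines)) stop_validation("CSV file has no header row: ", path)
  utils::read.csv(
    text = paste(lines, collapse = "\n"),
    colClasses = "character", check.names = FALSE,
    na.strings = character()
  )
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_validation(
      "missing required column(s) in ", path, ": ",
      paste(missing, collapse = ", ")
    )
  }
  df
}

check_unique_ids <- function(ids, what) {
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop_validation("duplicate ", what, ": '", dup[1], "'")
  }
  invisible(ids)
}

#' Read a corpus of clinical notes
#'
#' Notes are one record per document with the four fields `note_id`,
#' `patient_id`, `note_datetime` (ISO-8601) and `text`. JSONL carries one
#' JSON object per line; CSV carries the same columns with a mandatory
#' header.
#'
#' @param path path to the notes file.
#' @param format `"jsonl"` (default) or `"csv"`.
#' @param strict if `TRUE` (default) undecodable bytes are a hard failure;
#'   otherwise they are replaced with U+FFFD.
#' @return data.frame with character columns `note_id`, `patient_id`,
#'   `note_datetime`, `text`, in file order. Duplicate `note_id` values are
#'   an integrity error.
#' @export
#' @examples
#' path <- tempfile(fileext = ".jsonl")
#' writeLines(c(
#'   '{"note_id":"n1","patient_id":"p1","note_datetime":"2005-01-01","text":"FEV1 1.85 L"}'
#' ), path)
#' read_notes(path)
read_notes <- function(path, format = c("jsonl", "csv"), strict = TRUE) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- read_text_lines(path, strict = strict)
    lines <- lines[nzchar(trimws(lines))]
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      obj <- tryCatch(jsonlite::fromJSON(lines[i]),
        error = function(e) stop_validation("record ", i, ": invalid JSON (", conditionMessage(e), ")")
      )
      missing <- setdiff(NOTE_FIELDS, names(obj))
      if (length(missing)) {
        stop_validation(
          "record ", i, ": missing field(s) ",
          paste(missing, collapse = ", ")
        )
      }
      recs[[i]] <- lapply(obj[NOTE_FIELDS], as.character)
    }
    notes <- if (length(recs)) {
      as.data.frame(do.call(rbind, lapply(recs, unlist)), stringsAsFactors = FALSE)
    } else {
      as.data.frame(stats::setNames(rep(list(character()), 4), NOTE_FIELDS))
    }
    names(notes) <- NOTE_FIELDS
  } else {
    notes <- require_columns(read_csv_strict(path, strict = strict), NOTE_FIELDS, path)
    notes <- notes[NOTE_FIELDS]
  }
  empty_id <- which(!nzchar(notes$note_id))
  if (length(empty_id)) stop_validation("record ", empty_id[1], ": empty note_id")
  check_unique_ids(notes$note_id, "note_id")
  parse_timestamp(notes$note_datetime, "note_datetime")
  rownames(notes) <- NULL
  notes
}

#' Write a corpus of clinical notes
#'
#' Inverse of [read_notes()]; used by the synthetic generator and the CLI.
#'
#' @param notes data.frame as returned by [read_notes()].
#' @param path output path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_notes <- function(notes, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  ok <- tryCatch(
    {
      if (format == "jsonl") {
        lines <- vapply(seq_len(nrow(notes)), function(i) {
          jsonlite::toJSON(as.list(notes[i, NOTE_FIELDS]), auto_unbox = TRUE)
        }, character(1))
        writeLines(lines, path, useBytes = TRUE)
      } else {
        utils::write.csv(notes[NOTE_FIELDS], path, row.names = FALSE, quote = TRUE)
      }
      TRUE
    },
    error = function(e) e
  )
  if (!isTRUE(ok)) stop_io("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Read a structured FEV1 measurement table
#'
#' Emulates a warehouse pulmonary-function-test table: one row per
#' measurement with `patient_id`, `measure_datetime` and `fev1_value`.
#' A missing `fev1_value` is permitted and marks the row non-quantifiable;
#' a present value must be finite and strictly positive.
#'
#' @param path CSV path with columns `patient_id`, `measure_datetime`,
#'   `fev1_value`.
#' @param strict see [read_notes()].
#' @return data.frame with `fev1_value` numeric (`NA` when missing).
#' @export
read_structured <- function(path, strict = TRUE) {
  df <- require_columns(
    read_csv_strict(path, strict = strict),
    c("patient_id", "measure_datetime", "fev1_value"), path
  )
  raw <- trimws(df$fev1_value)
  raw[raw == "NA"] <- "" # tolerate R's default missing marker
  val <- suppressWarnings(as.numeric(raw))
  bad_parse <- which(nzchar(raw) & is.na(val))
  if (length(bad_parse)) {
    stop_validation("record ", bad_parse[1], ": unparseable fev1_value '", raw[bad_parse[1]], "'")
  }
  bad_range <- which(!is.na(val) & (!is.finite(val) | val <= 0))
  if (length(bad_range)) {
    stop_validation("record ", bad_range[1], ": fev1_value must be finite and > 0")
  }
  parse_timestamp(df$measure_datetime, "measure_datetime")
  out <- data.frame(
    patient_id = df$patient_id,
    measure_datetime = df$measure_datetime,
    fev1_value = val,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Read a reference-annotation table
#'
#' Emulates a chart-review reference standard: per note, whether a
#' quantifiable FEV1 is present and, if so, its value. The invariant
#' `reference_value` present iff `has_value` is enforced.
#'
#' @param path CSV path with columns `note_id`, `has_value`,
#'   `reference_value` (extra columns are ignored).
#' @param strict see [read_notes()].
#' @return data.frame with logical `has_value` and numeric
#'   `reference_value`.
#' @export
read_reference <- function(path, strict = TRUE) {
  df <- require_columns(
    read_csv_strict(path, strict = strict),
    c("note_id", "has_value", "reference_value"), path
  )
  hv <- trimws(tolower(df$has_value))
  if (!all(hv %in% c("true", "false"))) {
    stop_validation(
      "record ", which(!hv %in% c("true", "false"))[1],
      ": has_value must be true or false"
    )
  }
  has_value <- hv == "true"
  raw <- trimws(df$reference_value)
  raw[raw == "NA"] <- ""
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(has_value & (!nzchar(raw) | is.na(val)))
  if (length(bad)) {
    stop_validation("record ", bad[1], ": has_value is true but reference_value is missing")
  }
  bad <- which(!has_value & nzchar(raw))
  if (length(bad)) {
    stop_validation("record ", bad[1], ": has_value is false but reference_value is present")
  }
  val[!has_value] <- NA_real_
  check_unique_ids(df$note_id, "note_id in reference table")
  out <- data.frame(
    note_id = df$note_id,
    has_value = has_value,
    reference_value = val,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write extraction output
#'
#' One row per extracted FEV1 value, fixed column order, round-trips
#' losslessly through [read_extractions()].
#'
#' @param extractions data.frame as produced by [extract_corpus()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_extractions <- function(extractions, path) {
  df <- extractions[EXTRACTION_COLUMNS]
  # as.character() on doubles keeps up to 15 significant digits, so values
  # like 1.85 serialize as "1.85" and parse back to the identical double.
  df$value <- vapply(df$value, function(v) as.character(v), character(1))
  ok <- tryCatch(
    {
      utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
      TRUE
    },
    error = function(e) e
  )
  if (!isTRUE(ok)) stop_io("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Read extraction output written by [write_extractions()]
#'
#' @param path CSV path.
#' @param strict see [read_notes()].
#' @return data.frame with the extraction columns at their native types.
#' @export
read_extractions <- function(path, strict = TRUE) {
  df <- require_columns(read_csv_strict(path, strict = strict), EXTRACTION_COLUMNS, path)
  out <- data.frame(
    note_id = df$note_id,
    patient_id = df$patient_id,
    value = as.numeric(df$value),
    unit_guess = df$unit_guess,
    mention_start = as.integer(df$mention_start),
    mention_end = as.integer(df$mention_end),
    value_start = as.integer(df$value_start),
    window_text = df$window_text,
    multi_mention = toupper(df$multi_mention) == "TRUE",
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
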