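# Patient-level yield analysis: combine structured-source FEV1 availability
# with note-extracted values to quantify how many patients the text tool
# adds, plus per-patient first values and histogram summaries for
# distribution comparison.

#' Patients with a quantifiable structured FEV1
#'
#' @param structured data.frame from [read_structured()].
#' @return character vector of unique patient ids having at least one
#'   present, finite, positive `fev1_value`.
#' @export
patients_with_quantifiable <- function(structured) {
  ok <- !is.na(structured$fev1_value) &
    is.finite(structured$fev1_value) & structured$fev1_value > 0
  sort(unique(structured$patient_id[ok]))
}

#' Merge structured and note-extracted FEV1 yield
#'
#' A patient present in both sources counts once, under structured; the
#' text tool's contribution is the set of patients whose values were
#' otherwise unavailable. The percent increase is reported against the
#' combined total.
#'
#' @param structured_ids patient ids with quantifiable structured FEV1.
#' @param extracted_ids patient ids with at least one note-extracted FEV1.
#' @return object of class `yield_summary`: list with `n_structured`,
#'   `n_added`, `n_total`, `pct_increase` (one decimal,
#'   100 * n_added / n_total) and `pct_display` (rounded to integer).
#' @export
#' @examples
#' y <- merge_yield(sprintf("s%d", 1:12425), sprintf("e%d", 1:3849))
#' y$n_total # 16274
#' y$pct_display # 24
merge_yield <- function(structured_ids, extracted_ids) {
  s <- unique(as.character(structured_ids))
  e <- unique(as.character(extracted_ids))
  n_structured <- length(s)
  n_added <- length(setdiff(e, s))
  n_total <- n_structured + n_added
  pct <- if (n_total > 0) 100 * n_added / n_total else 0
  structure(
    list(
      n_structured = n_structured,
      n_added = n_added,
      n_total = n_total,
      pct_increase = round(pct, 1),
      pct_display = as.integer(round(pct))
    ),
    class = "yield_summary"
  )
}

#' @export
print.yield_summary <- function(x, ...) {
  cat("FEV1 yield: ", x$n_structured, " structured + ", x$n_added,
    " added by text extraction = ", x$n_total,
    " patients (", x$pct_display, "% increase)\n",
    sep = ""
  )
  invisible(x)
}

#' First extracted FEV1 per patient
#'
#' Per patient, the extraction from the earliest note; ties on
#' `note_datetime` are broken by the lexicographically smallest `note_id`,
#' so the result is deterministic.
#'
#' @param extractions data.frame of extraction records.
#' @param notes the note corpus the extractions came from (supplies
#'   timestamps); an extraction referencing a note absent from `notes` is
#'   an integrity error.
#' @return data.frame with one extraction row per patient plus a
#'   `note_datetime` column, ordered by `patient_id`.
#' @export
first_per_patient <- function(extractions, notes) {
  stray <- setdiff(extractions$note_id, notes$note_id)
  if (length(stray)) {
    stop_validation("extraction references unknown note_id: '", stray[1], "'")
  }
  if (!nrow(extractions)) {
    out <- extractions
    out$note_datetime <- character()
    return(out)
  }
  pos <- match(extractions$note_id, notes$note_id)
  ext <- extractions
  ext$note_datetime <- notes$note_datetime[pos]
  dt <- parse_timestamp(ext$note_datetime, "note_datetime")
  ord <- order(ext$patient_id, dt, ext$note_id)
  ext <- ext[ord, ]
  out <- ext[!duplicated(ext$patient_id), ]
  rownames(out) <- NULL
  out
}

#' Histogram summary of FEV1 values
#'
#' Left-closed, right-open bins; the last bin is closed so the upper edge
#' is included. Values outside the edges (or non-finite) are tallied in a
#' separate overflow count, never silently dropped:
#' `sum(counts) + overflow == length(values)`.
#'
#' @param values numeric vector.
#' @param bin_edges strictly ascending numeric vector of at least two
#'   edges. Conventional display edges are `seq(0, 160, 10)` for
#'   percent-predicted and `seq(0, 8, 0.5)` for liters.
#' @return list with `bin_edges`, `counts`, `n` (= sum of counts) and
#'   `overflow`.
#' @export
distribution_summary <- function(values, bin_edges) {
  bin_edges <- as.numeric(bin_edges)
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0)) {
    stop_validation("bin_edges must be strictly ascending with at least 2 edges")
  }
  values <- as.numeric(values)
  finite <- is.finite(values)
  in_range <- finite & values >= bin_edges[1] & values <= bin_edges[length(bin_edges)]
  k <- length(bin_edges) - 1L
  counts <- tabulate(
    findInterval(values[in_range], bin_edges, rightmost.closed = TRUE),
    nbins = k
  )
  list(
    bin_edges = bin_edges,
    counts = counts,
    n = sum(counts),
    overflow = sum(!in_range)
  )
}
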