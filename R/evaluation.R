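# Scoring of extractions against reference annotations: record-level
# confusion counts, precision (positive predictive value) with a Wilson
# score interval, recall, F-measure, value-level accuracy on true
# positives, and Spearman rank agreement between extracted and reference
# values. The scoring unit is the note: a note with any emitted extraction
# counts as tool-positive.

#' Record-level confusion counts
#'
#' Only notes present in the reference table are scored; an extraction for
#' a note absent from the references is an integrity error. Reference notes
#' never extracted count toward `fn`/`tn`.
#'
#' @param extractions data.frame of extraction records.
#' @param references data.frame from [read_reference()] (or the gold table
#'   of [generate_corpus()]).
#' @return object of class `confusion_counts`: list with `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
classify_records <- function(extractions, references) {
  check_unique_ids(references$note_id, "note_id in reference table")
  ext_ids <- unique(extractions$note_id)
  stray <- setdiff(ext_ids, references$note_id)
  if (length(stray)) {
    stop_validation("extraction for note absent from references: '", stray[1], "'")
  }
  tool_pos <- references$note_id %in% ext_ids
  ref_pos <- references$has_value
  structure(
    list(
      tp = sum(tool_pos & ref_pos),
      fp = sum(tool_pos & !ref_pos),
      fn = sum(!tool_pos & ref_pos),
      tn = sum(!tool_pos & !ref_pos)
    ),
    class = "confusion_counts"
  )
}

#' Precision, recall and F-measure from confusion counts
#'
#' Undefined quantities (zero denominators) are reported as `NA`, never
#' coerced to zero.
#'
#' @param counts a `confusion_counts` object (or list with `tp`, `fp`,
#'   `fn`).
#' @return list with `precision` (= PPV), `recall`, `f_measure`.
#' @export
precision_recall_f <- function(counts) {
  tp <- counts$tp
  precision <- if (tp + counts$fp > 0) tp / (tp + counts$fp) else NA_real_
  recall <- if (tp + counts$fn > 0) tp / (tp + counts$fn) else NA_real_
  f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  list(precision = precision, recall = recall, f_measure = f)
}

#' Wilson score confidence interval for a proportion
#'
#' Chosen over the Wald interval because it behaves sensibly at proportions
#' near 0 or 1 — exactly where a high-precision extraction tool lives.
#' Bounds are clipped to `[0, 1]`.
#'
#' @param successes number of successes.
#' @param n number of trials (> 0).
#' @param level confidence level (default 0.95).
#' @return numeric vector `c(low, high)`.
#' @export
proportion_ci <- function(successes, n, level = 0.95) {
  if (length(n) != 1L || is.na(n) || n <= 0) stop_validation("n must be > 0")
  if (successes < 0 || successes > n) stop_validation("need 0 <= successes <= n")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(
    low = max(0, center - half),
    high = min(1, center + half)
  )
}

# First extraction per note, in document (row) order.
first_extraction_per_note <- function(extractions) {
  extractions[!duplicated(extractions$note_id), , drop = FALSE]
}

# Paired extracted/reference values over true-positive notes.
tp_value_pairs <- function(extractions, references) {
  ext <- first_extraction_per_note(extractions)
  pos <- references[references$has_value, , drop = FALSE]
  keep <- ext$note_id %in% pos$note_id
  ext <- ext[keep, , drop = FALSE]
  data.frame(
    note_id = ext$note_id,
    extracted = ext$value,
    reference = pos$reference_value[match(ext$note_id, pos$note_id)],
    stringsAsFactors = FALSE
  )
}

#' Value-level accuracy on true-positive notes
#'
#' The fraction of true-positive notes whose extracted value matches the
#' reference within a relative tolerance:
#' `|extracted - reference| <= tolerance * max(1, reference)`. The default
#' 0.5% covers decimal re-formatting, not transcription differences; set
#' `tolerance = 0` for exact matching.
#'
#' @param extractions data.frame of extraction records.
#' @param references reference-annotation data.frame.
#' @param tolerance relative tolerance (default 0.005).
#' @return proportion in `[0, 1]`, or `NA` when there are no true
#'   positives.
#' @export
value_accuracy <- function(extractions, references, tolerance = 0.005) {
  pairs <- tp_value_pairs(extractions, references)
  if (!nrow(pairs)) return(NA_real_)
  ok <- abs(pairs$extracted - pairs$reference) <=
    tolerance * pmax(1, pairs$reference)
  mean(ok)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. Undefined (`NA`) for
#' fewer than two pairs or zero rank variance in either coordinate.
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) return(NA_real_)
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Evaluate extractions against a reference standard
#'
#' Composes [classify_records()], [precision_recall_f()],
#' [proportion_ci()] (on the tool-positive calls, i.e. the PPV),
#' [value_accuracy()] and [spearman_rho()] (both over true-positive notes).
#'
#' @param extractions data.frame of extraction records.
#' @param references reference-annotation data.frame (nonempty).
#' @param tolerance relative tolerance for [value_accuracy()].
#' @param conf_level confidence level for the PPV interval.
#' @return object of class `eval_metrics`: list with the confusion counts,
#'   `n_scored`, `precision`, `recall`, `f_measure`, `ppv_ci_low`,
#'   `ppv_ci_high`, `value_accuracy`, `spearman_rho`, `n_value_pairs`.
#' @export
evaluate <- function(extractions, references, tolerance = 0.005, conf_level = 0.95) {
  if (is.null(references) || !nrow(references)) {
    stop_validation("reference set is empty")
  }
  counts <- classify_records(extractions, references)
  prf <- precision_recall_f(counts)
  n_pos_calls <- counts$tp + counts$fp
  ci <- if (n_pos_calls > 0) {
    proportion_ci(counts$tp, n_pos_calls, conf_level)
  } else {
    c(low = NA_real_, high = NA_real_)
  }
  pairs <- tp_value_pairs(extractions, references)
  structure(
    list(
      tp = counts$tp, fp = counts$fp, fn = counts$fn, tn = counts$tn,
      n_scored = counts$tp + counts$fp + counts$fn + counts$tn,
      precision = prf$precision,
      recall = prf$recall,
      f_measure = prf$f_measure,
      ppv_ci_low = unname(ci["low"]),
      ppv_ci_high = unname(ci["high"]),
      value_accuracy = value_accuracy(extractions, references, tolerance),
      spearman_rho = spearman_rho(pairs$extracted, pairs$reference),
      n_value_pairs = nrow(pairs)
    ),
    class = "eval_metrics"
  )
}

#' @export
print.eval_metrics <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "NA", formatC(v, digits = 4, format = "f"))
  cat("Record-level evaluation over ", x$n_scored, " notes\n",
    "  tp=", x$tp, " fp=", x$fp, " fn=", x$fn, " tn=", x$tn, "\n",
    "  precision (PPV): ", fmt(x$precision),
    "  [", fmt(x$ppv_ci_low), ", ", fmt(x$ppv_ci_high), "]\n",
    "  recall:          ", fmt(x$recall), "\n",
    "  F-measure:       ", fmt(x$f_measure), "\n",
    "  value accuracy:  ", fmt(x$value_accuracy),
    " over ", x$n_value_pairs, " true-positive notes\n",
    "  Spearman rho:    ", fmt(x$spearman_rho), "\n",
    sep = ""
  )
  invisible(x)
}
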