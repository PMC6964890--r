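# Shared internal helpers: typed error conditions, ISO-8601 timestamps,
# scoped RNG. Error classes map onto CLI exit codes (validation -> 1, io -> 2).

stop_validation <- function(...) {
  stop(structure(
    class = c("spirotext_validation_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

stop_io <- function(...) {
  stop(structure(
    class = c("spirotext_io_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

#' Parse ISO-8601 timestamps
#'
#' Accepts `YYYY-MM-DD`, `YYYY-MM-DDTHH:MM:SS` or the space-separated
#' equivalent. Date-only values are completed with midnight so every
#' timestamp sorts unambiguously. All times are interpreted as UTC; clinical
#' note exports rarely carry zone information and only ordering matters here.
#'
#' @param x character vector of timestamps.
#' @param what label used in the error message when parsing fails.
#' @return `POSIXct` vector (UTC).
#' @keywords internal
parse_timestamp <- function(x, what = "timestamp") {
  x <- as.character(x)
  date_only <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  x[date_only] <- paste0(x[date_only], "T00:00:00")
  x <- sub("^(\\d{4}-\\d{2}-\\d{2}) ", "\\1T", x)
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop_validation("unparseable ", what, " at position ", bad[1], ": '", x[bad[1]], "'")
  }
  out
}

# Evaluate `code` under a fixed, portable RNG state, restoring the caller's
# stream afterwards. Mersenne-Twister + inversion + rejection sampling are
# pinned explicitly so corpora are byte-identical across platforms and R
# versions.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  suppressWarnings(set.seed(seed,
    kind = "Mersenne-Twister",
    normal.kind = "Inversion", sample.kind = "Rejection"
  ))
  force(code)
}

# 0-based half-open [start, end) slice of a scalar string.
slice0 <- function(text, start, end) {
  substr(text, start + 1L, end)
}
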