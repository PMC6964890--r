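# Independent oracles used by the property suites. Each one is written as a
# direct, character-at-a-time (or closed-form) computation, deliberately
# sharing no code with the implementation it checks.

# Brute-force window scanner: walk every character position in the window,
# grow a numeric token by hand, apply the date-like skip and ratio guard.
oracle_scan <- function(text, mention_end0, window = 20L,
                        ratio_guard = TRUE, skip_datelike = TRUE) {
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  is_digit <- function(ch) ch >= "0" && ch <= "9"
  # A digit is a token START only when it does not continue an earlier
  # token in the window: the previous char must not be a digit, nor the
  # "." of a decimal already begun by a digit. Characters at or before the
  # mention end are outside the scan region and never count as context.
  is_start <- function(p) {
    if (!is_digit(chars[p])) return(FALSE)
    if (p - 1L <= mention_end0) return(TRUE)
    if (is_digit(chars[p - 1L])) return(FALSE)
    !(chars[p - 1L] == "." && p - 2L > mention_end0 && is_digit(chars[p - 2L]))
  }
  p <- mention_end0 + 1L # 1-based scan position
  last <- mention_end0 + window + 1L # rel offset of token start <= window
  while (p <= min(n, last)) {
    if (is_start(p)) {
      q <- p
      while (q + 1L <= n && is_digit(chars[q + 1L])) q <- q + 1L
      if (q + 2L <= n && chars[q + 1L] == "." && is_digit(chars[q + 2L])) {
        q <- q + 2L
        while (q + 1L <= n && is_digit(chars[q + 1L])) q <- q + 1L
      }
      if (q + 1L <= n && chars[q + 1L] == "%") q <- q + 1L
      datelike <- skip_datelike && (
        (q + 2L <= n && chars[q + 1L] == "/" && is_digit(chars[q + 2L])) ||
          (p - 1L > mention_end0 && chars[p - 1L] == "/")
      )
      if (!datelike) {
        between <- if (p > mention_end0 + 1L) {
          paste(chars[(mention_end0 + 1L):(p - 1L)], collapse = "")
        } else {
          ""
        }
        if (ratio_guard && grepl("fvc", between, ignore.case = TRUE)) {
          return(NULL)
        }
        return(list(
          raw_token = paste(chars[p:q], collapse = ""),
          value_start = p - 1L
        ))
      }
      p <- p + 1L
    } else {
      p <- p + 1L
    }
  }
  NULL
}

# Random clinical-looking strings stressing the scanner: surface variants,
# fever words, ratio contexts, dates, decimals, percents, noise. Pieces are
# joined by "", " " or " " at random so both clean word boundaries and
# tricky adjacencies occur.
random_scan_string <- function() {
  pool <- c(
    "FEV1", "FEV-1", "fev_1", "FEV 1", "fever", "FVC", "FEV1/FVC",
    "/", " ", "  ", ".", "%", "-", ":", "of", "was", "pred",
    "0", "1", "7", "12", "58", "101", "350", "1.85", "2.40", "0.55",
    "12/04", "12/04/2019", "58%", "xx", "L"
  )
  pieces <- sample(pool, sample(4:12, 1), replace = TRUE)
  seps <- sample(c("", " ", " "), length(pieces), replace = TRUE)
  paste0(pieces, seps, collapse = "")
}

# Average ranks and the Pearson product-moment formula applied to them —
# an independent route to Spearman's coefficient with ties.
oracle_avg_rank <- function(v) {
  vapply(v, function(x) sum(v < x) + (sum(v == x) + 1) / 2, numeric(1))
}

oracle_spearman <- function(x, y) {
  rx <- oracle_avg_rank(x)
  ry <- oracle_avg_rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Tiny fixture builders -----------------------------------------------------

make_notes <- function(texts, patient_id = NULL, datetime = NULL) {
  n <- length(texts)
  data.frame(
    note_id = sprintf("n%03d", seq_len(n)),
    patient_id = if (is.null(patient_id)) sprintf("p%03d", seq_len(n)) else patient_id,
    note_datetime = if (is.null(datetime)) rep("2005-06-15T12:00:00", n) else datetime,
    text = texts,
    stringsAsFactors = FALSE
  )
}

make_reference <- function(note_id, has_value, reference_value = NULL) {
  if (is.null(reference_value)) {
    reference_value <- ifelse(has_value, 1.0, NA_real_)
  }
  data.frame(
    note_id = note_id, has_value = has_value,
    reference_value = reference_value, stringsAsFactors = FALSE
  )
}
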