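# First pass of the two-step approach: a keyword index over the corpus and a
# candidate filter that retrieves every note containing an FEV-prefixed
# token. This emulates the full-text (keyword) index a relational database
# engine would use as a cheap pre-filter before pattern processing; the
# filter is deliberately permissive ("fever" passes), leaving rejection to
# the pattern pass so the division of labor between the passes is preserved.

#' Build a keyword index over a note corpus
#'
#' Tokens are maximal runs of alphanumeric characters, case-folded —
#' mirroring word-breaker behavior of full-text engines, so `"FEV-1"` and
#' `"FEV_1"` both yield an `"fev"`-prefixed token.
#'
#' @param notes data.frame of notes (see [read_notes()]).
#' @return object of class `keyword_index`: list with `token_map` (named
#'   list, case-folded token -> character vector of note ids) and
#'   `token_count`.
#' @export
#' @examples
#' notes <- data.frame(
#'   note_id = "n1", patient_id = "p1",
#'   note_datetime = "2005-01-01", text = "FEV1 2.1"
#' )
#' idx <- build_keyword_index(notes)
#' sort(names(idx$token_map)) # "1" "2" "fev1"
build_keyword_index <- function(notes) {
  toks <- lapply(notes$text, function(t) {
    unique(regmatches(tolower(t), gregexpr("[[:alnum:]]+", tolower(t)))[[1]])
  })
  n_per_note <- lengths(toks)
  token_map <- split(
    rep(notes$note_id, n_per_note),
    unlist(toks, use.names = FALSE)
  )
  token_map <- lapply(token_map, unique)
  structure(
    list(token_map = token_map, token_count = length(token_map)),
    class = "keyword_index"
  )
}

#' @export
print.keyword_index <- function(x, ...) {
  cat("<keyword_index> ", x$token_count, " distinct tokens\n", sep = "")
  invisible(x)
}

#' Retrieve candidate notes by keyword
#'
#' Prefix mode (the default) returns the ids of all notes containing any
#' token whose case-folded form begins with the keyword, so `"fev1"`,
#' `"fev"` and `"fever"` all pass; false positives such as fever mentions
#' are rejected downstream by the pattern pass. Exact mode requires token
#' equality.
#'
#' @param index a `keyword_index`.
#' @param keyword nonempty search keyword; case-insensitive.
#' @param mode `"prefix"` (default) or `"exact"`.
#' @return sorted character vector of note ids (a subset of corpus ids).
#' @export
find_candidates <- function(index, keyword = "fev", mode = c("prefix", "exact")) {
  mode <- match.arg(mode)
  if (!is.character(keyword) || length(keyword) != 1L || !nzchar(keyword)) {
    stop_validation("keyword must be a nonempty string")
  }
  kw <- tolower(keyword)
  tokens <- names(index$token_map)
  hit <- if (mode == "prefix") startsWith(tokens, kw) else tokens == kw
  ids <- unlist(index$token_map[hit], use.names = FALSE)
  if (is.null(ids)) character() else sort(unique(ids))
}
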