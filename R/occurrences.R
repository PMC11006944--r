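#' Positions at which a context occurs
#'
#' An occurrence of the context `w` ends at step `n` when the last `l(w)`
#' symbols up to and including `X_n` equal `w`.
#'
#' @param kicks Integer symbol sequence.
#' @param w Context (integer vector or label string); must be non-empty.
#' @return Strictly increasing integer vector of end positions (possibly
#'   empty).
#' @export
occurrence_ends <- function(kicks, w) {
  w <- as_context(w)
  m <- length(w)
  if (m < 1L) stop("occurrence_ends() requires a non-empty context")
  n <- length(kicks)
  if (n < m) return(integer(0))
  ends <- seq.int(m, n)
  ok <- rep(TRUE, length(ends))
  for (i in seq_len(m)) {
    ok <- ok & (kicks[ends - m + i] == w[i])
  }
  ends[ok]
}

# Label of the longest matching context of `tree` ending at each position of
# `kicks`; NA_character_ where no context matches (e.g. a too-short past).
# Suffix-freeness makes the match unique, so assignment order is irrelevant.
context_at_each_position <- function(kicks, tree) {
  out <- rep(NA_character_, length(kicks))
  for (lab in tree$contexts) {
    if (!nzchar(lab)) {
      out[is.na(out)] <- lab
      next
    }
    out[occurrence_ends(kicks, lab)] <- lab
  }
  out
}

# All distinct length-m substrings occurring in `kicks`, as labels.
occurring_strings <- function(kicks, m) {
  n <- length(kicks)
  if (n < m || m < 1L) return(character(0))
  windows <- vapply(seq.int(m, n), function(e) {
    paste(kicks[(e - m + 1L):e], collapse = "")
  }, character(1))
  unique(windows)
}
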