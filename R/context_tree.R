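#' Coerce to a context
#'
#' A context is a finite sequence of past symbols stored oldest-first, so the
#' label `"21"` means "the symbol before last was 2, the last symbol was 1".
#' The empty sequence (the root of a context tree) is a valid context and
#' represents a memoryless chain.
#'
#' @param x An integer vector of symbols (oldest first), or a single string of
#'   one-digit symbol labels such as `"21"`. `""` and `integer(0)` both denote
#'   the root.
#' @return An integer vector of symbols, oldest first (possibly empty).
#' @examples
#' as_context("21")
#' as_context(c(2L, 1L))
#' as_context("") # the root
#' @export
as_context <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    if (!nzchar(x)) return(integer(0))
    digits <- strsplit(x, "", fixed = TRUE)[[1L]]
    if (!all(grepl("^[0-9]$", digits))) {
      stop("context labels must consist of one-digit symbols, got ", sQuote(x))
    }
    return(as.integer(digits))
  }
  if (is.numeric(x)) {
    if (length(x) && any(x != floor(x))) stop("context symbols must be integers")
    return(as.integer(x))
  }
  stop("cannot interpret an object of class ", class(x)[1L], " as a context")
}

#' Label of a context
#'
#' @param x A context (integer vector or label string).
#' @return A single string, oldest symbol first; `""` for the root.
#' @export
context_label <- function(x) {
  paste(as_context(x), collapse = "")
}

#' Compare two equal-length sequences in reverse lexicographic order
#'
#' Sequences are compared starting from the most recent symbol (the last
#' position) and moving backwards in time: `u < v` if the last symbol of `u`
#' is smaller, or if the two sequences agree on a suffix and `u` has the
#' smaller symbol at the first (most recent) position where they differ.
#' This is the order in which the tree estimator processes its candidate
#' queue.
#'
#' @param u,v Contexts of equal length (integer vectors or label strings).
#' @return `-1L` if `u < v`, `0L` if equal, `1L` if `u > v`.
#' @examples
#' reverse_lex_compare("10", "01") # -1: last symbols 0 < 1
#' reverse_lex_compare("01", "21") # -1: last symbols tie, then 0 < 2
#' @export
reverse_lex_compare <- function(u, v) {
  u <- as_context(u)
  v <- as_context(v)
  if (length(u) != length(v)) {
    stop("reverse_lex_compare() requires sequences of equal length (got ",
         length(u), " and ", length(v), ")")
  }
  for (i in rev(seq_along(u))) {
    if (u[i] < v[i]) return(-1L)
    if (u[i] > v[i]) return(1L)
  }
  0L
}

#' Sort equal-length contexts into reverse lexicographic order
#'
#' @param labels Character vector of equal-length context labels.
#' @return `labels` sorted ascending under [reverse_lex_compare()].
#' @export
reverse_lex_sort <- function(labels) {
  if (!length(labels)) return(labels)
  len <- unique(nchar(labels))
  if (length(len) != 1L) stop("all labels must have the same length")
  reversed <- vapply(strsplit(labels, "", fixed = TRUE),
                     function(d) paste(rev(d), collapse = ""), character(1))
  labels[order(reversed, method = "radix")]
}

#' Is a set of contexts suffix-free?
#'
#' A valid context tree is suffix-free: no context is a proper suffix of
#' another (equivalently, the contexts are the leaves of a rooted labelled
#' tree).
#'
#' @param contexts Character vector of context labels (or list of contexts).
#' @return `TRUE` iff no member is a proper suffix of another member.
#' @examples
#' is_suffix_free(c("0", "2", "01", "11", "21")) # TRUE
#' is_suffix_free(c("1", "01"))                  # FALSE
#' @export
is_suffix_free <- function(contexts) {
  labels <- vapply(as.list(contexts), context_label, character(1))
  labels <- unique(labels)
  if (length(labels) < 2L) return(TRUE)
  for (i in seq_along(labels)) {
    for (j in seq_along(labels)) {
      if (i == j) next
      u <- labels[i]
      v <- labels[j]
      if (nchar(u) < nchar(v) && substring(v, nchar(v) - nchar(u) + 1L) == u) {
        return(FALSE)
      }
      # the root is a proper suffix of any non-empty context
      if (!nzchar(u) && nzchar(v)) return(FALSE)
    }
  }
  TRUE
}

#' Construct a context tree
#'
#' @param contexts Character vector of context labels (oldest symbol first),
#'   or a list of integer-vector contexts. Must be suffix-free.
#' @param alphabet Integer vector of admissible symbols, default `0:2`
#'   (left / centre / right).
#' @return An object of class `context_tree` with elements `contexts`
#'   (character, sorted by length then reverse-lexicographically) and
#'   `alphabet`.
#' @examples
#' context_tree(c("0", "2", "01", "11", "21"))
#' @export
context_tree <- function(contexts, alphabet = 0:2) {
  alphabet <- sort(unique(as.integer(alphabet)))
  if (!length(alphabet)) stop("alphabet must be non-empty")
  labels <- unique(vapply(as.list(contexts), context_label, character(1)))
  for (lab in labels) {
    syms <- as_context(lab)
    if (!all(syms %in% alphabet)) {
      stop("context ", sQuote(lab), " uses symbols outside the alphabet")
    }
  }
  if (!is_suffix_free(labels)) {
    stop("context set is not suffix-free")
  }
  ord <- order(nchar(labels))
  labels <- unlist(lapply(split(labels[ord], nchar(labels)[ord]),
                          reverse_lex_sort), use.names = FALSE)
  structure(list(contexts = as.character(labels), alphabet = alphabet),
            class = "context_tree")
}

#' @export
print.context_tree <- function(x, ...) {
  labs <- x$contexts
  labs[!nzchar(labs)] <- "<root>"
  cat("Context tree over alphabet {", paste(x$alphabet, collapse = ","),
      "} with ", length(labs), " context(s):\n  ",
      paste(labs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Depth of a context tree
#'
#' @param tree A `context_tree`.
#' @return The maximum context length (0 for the root-only tree).
#' @export
tree_depth <- function(tree) {
  stopifnot(inherits(tree, "context_tree"))
  if (!length(tree$contexts)) return(0L)
  max(nchar(tree$contexts))
}

#' Equality of context trees (same context set and alphabet)
#'
#' @param a,b `context_tree` objects.
#' @return Logical.
#' @export
same_tree <- function(a, b) {
  stopifnot(inherits(a, "context_tree"), inherits(b, "context_tree"))
  setequal(a$contexts, b$contexts) && identical(a$alphabet, b$alphabet)
}

#' Longest context matching the end of a past sequence
#'
#' Scans the tree for the unique member that is a suffix of `past`.
#' Suffix-freeness guarantees at most one member can match.
#'
#' @param tree A `context_tree`.
#' @param past Integer vector of past symbols, oldest first (non-empty
#'   unless the tree contains the root).
#' @return The matching context label (a string), or `NULL` when no member
#'   of the tree is a suffix of `past`.
#' @examples
#' tau <- context_tree(c("0", "2", "01", "11", "21"))
#' longest_context_suffix(tau, c(0, 2))    # "2"
#' longest_context_suffix(tau, c(2, 1))    # "21"
#' longest_context_suffix(tau, 1)          # NULL: 1 alone is not a leaf
#' @export
longest_context_suffix <- function(tree, past) {
  stopifnot(inherits(tree, "context_tree"))
  past <- as_context(past)
  np <- length(past)
  best <- NULL
  for (lab in tree$contexts) {
    w <- as_context(lab)
    lw <- length(w)
    if (lw > np) next
    if (lw == 0L || identical(past[(np - lw + 1L):np], w)) {
      if (is.null(best) || lw > nchar(best)) best <- lab
    }
  }
  best
}

#' Construct a probabilistic context tree
#'
#' The pair of a suffix-free context set and a family of next-symbol
#' transition distributions indexed by context.
#'
#' @param tree A `context_tree`, or anything [context_tree()] accepts.
#' @param transition A numeric matrix with one row per context (rownames =
#'   context labels) and one column per alphabet symbol, or a named list of
#'   probability vectors. Each row must be non-negative and sum to 1
#'   (tolerance `1e-12`).
#' @param alphabet Alphabet, used only when `tree` is not already a
#'   `context_tree`.
#' @return An object of class `c("probabilistic_context_tree",
#'   "context_tree")` with an extra `transition` matrix element.
#' @export
probabilistic_context_tree <- function(tree, transition, alphabet = 0:2) {
  if (!inherits(tree, "context_tree")) tree <- context_tree(tree, alphabet)
  if (is.list(transition)) {
    transition <- do.call(rbind, transition)
  }
  transition <- as.matrix(transition)
  if (is.null(rownames(transition))) {
    stop("transition rows must be named by context label")
  }
  missing_rows <- setdiff(tree$contexts, rownames(transition))
  if (length(missing_rows)) {
    stop("missing transition rows for context(s): ",
         paste(sQuote(missing_rows), collapse = ", "))
  }
  transition <- transition[tree$contexts, , drop = FALSE]
  if (ncol(transition) != length(tree$alphabet)) {
    stop("transition must have one column per alphabet symbol")
  }
  colnames(transition) <- as.character(tree$alphabet)
  if (any(transition < 0)) stop("transition probabilities must be non-negative")
  sums <- rowSums(transition)
  if (any(abs(sums - 1) > 1e-12)) {
    stop("transition rows must sum to 1 (max deviation ",
         format(max(abs(sums - 1))), ")")
  }
  out <- unclass(tree)
  out$transition <- transition
  structure(out, class = c("probabilistic_context_tree", "context_tree"))
}

#' @export
print.probabilistic_context_tree <- function(x, ...) {
  NextMethod()
  cat("Transition probabilities:\n")
  print(round(x$transition, 6))
  invisible(x)
}

#' The generating model of the goalkeeper-game kick sequence
#'
#' The penalty taker's kicks follow a stochastic chain with memory of
#' variable length over the directions \{0, 1, 2\} (left, centre, right).
#' The chain is a concatenation of triplets `0 * 1`, where `*` is 2 with
#' probability `p` and 1 with probability `1 - p`, independently of the
#' past. Its context tree is \{0, 2, 01, 11, 21\}: after a 0 the next
#' symbol is 2 w.p. `p` (else 1); after contexts 2 and 01 the next symbol
#' is always 1; after 11 and 21 it is always 0.
#'
#' @param p Probability that the middle symbol of a triplet is 2
#'   (default 0.7).
#' @return A [probabilistic_context_tree()].
#' @examples
#' penalty_taker_tree()
#' @export
penalty_taker_tree <- function(p = 0.7) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  probabilistic_context_tree(
    context_tree(c("0", "2", "01", "11", "21"), alphabet = 0:2),
    rbind("0"  = c(0, 1 - p, p),
          "2"  = c(0, 1, 0),
          "01" = c(0, 1, 0),
          "11" = c(1, 0, 0),
          "21" = c(1, 0, 0)))
}

#' Write a context tree to JSON
#'
#' Serialises a plain or probabilistic context tree as a JSON object with
#' fields `alphabet`, `contexts` (digit strings, oldest symbol first) and,
#' when present, `transition` (a map from context label to probability
#' vector ordered by alphabet symbol).
#'
#' @param tree A `context_tree` or `probabilistic_context_tree`.
#' @param path File path to write to.
#' @return `path`, invisibly.
#' @export
write_context_tree <- function(tree, path) {
  stopifnot(inherits(tree, "context_tree"))
  obj <- list(alphabet = tree$alphabet, contexts = tree$contexts)
  if (!is.null(tree$transition)) {
    obj$transition <- stats::setNames(
      lapply(rownames(tree$transition),
             function(r) unname(tree$transition[r, ])),
      rownames(tree$transition))
  }
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a context tree from JSON
#'
#' @param path File written by [write_context_tree()].
#' @return A `context_tree`, or a `probabilistic_context_tree` when the file
#'   carries transition probabilities.
#' @export
read_context_tree <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  contexts <- as.character(obj$contexts)
  contexts[is.na(contexts)] <- ""
  tree <- context_tree(contexts, alphabet = as.integer(obj$alphabet))
  if (is.null(obj$transition)) return(tree)
  trans <- do.call(rbind, obj$transition)
  rn <- names(obj$transition)
  rn[is.na(rn) | rn == "NA"] <- ""
  rownames(trans) <- rn
  probabilistic_context_tree(tree, trans)
}
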