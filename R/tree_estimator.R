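#' Response times associated with a context
#'
#' Collects `T_{n+1}` for every occurrence of `w` ending at step `n`, in
#' occurrence order. Occurrences ending at the final trial carry no
#' response to the next prediction and are excluded.
#'
#' @param kicks Integer symbol sequence.
#' @param response_times Aligned numeric response-time sequence.
#' @param w Context (non-empty).
#' @return Numeric vector (possibly empty) of response times.
#' @examples
#' collect_context_rt_samples(c(0, 2, 1, 0, 1, 1), seq(0.1, 0.6, by = 0.1), "0")
#' @export
collect_context_rt_samples <- function(kicks, response_times, w) {
  stopifnot(length(kicks) == length(response_times))
  ends <- occurrence_ends(kicks, w)
  ends <- ends[ends < length(kicks)]
  response_times[ends + 1L]
}

#' Sibling family of a context
#'
#' The family `F(w)` contains every sequence occurring in the sample that is
#' obtained by prepending one alphabet symbol to the suffix
#' `(w_{-l(w)+1}, ..., w_{-1})` of `w`; `w` itself belongs to `F(w)`
#' whenever it occurs.
#'
#' @param kicks Integer symbol sequence.
#' @param w Context of length at least 1.
#' @param alphabet Alphabet, default `0:2`.
#' @return Character vector of occurring sibling labels, in reverse
#'   lexicographic order.
#' @export
sibling_family <- function(kicks, w, alphabet = 0:2) {
  w <- as_context(w)
  if (length(w) < 1L) stop("sibling_family() requires a non-empty context")
  suffix <- if (length(w) > 1L) paste(w[-1L], collapse = "") else ""
  candidates <- paste0(alphabet, suffix)
  present <- vapply(candidates, function(lab) {
    length(occurrence_ends(kicks, lab)) > 0L
  }, logical(1))
  reverse_lex_sort(candidates[present])
}

#' Kolmogorov-Smirnov decision on a sibling family
#'
#' Runs the two-sample Kolmogorov-Smirnov test on every unordered pair of
#' siblings whose response-time samples both contain at least `min_count`
#' observations, and rejects equality of the family's distributions as soon
#' as any pair differs at level `alpha` ("at least two leaves" rule). With
#' fewer than two testable siblings the family is retained for lack of
#' evidence, with a flag.
#'
#' @param samples Named list of numeric response-time samples, one per
#'   sibling.
#' @param alpha Significance level (default 0.05).
#' @param min_count Minimum sample size for a sibling to enter testing
#'   (default 5).
#' @return A list with elements `decision` (`"reject"` or `"retain"`),
#'   `tests` (data frame of pairwise D statistics and p-values), `tested`
#'   (labels that entered testing) and `flagged` (`TRUE` when fewer than two
#'   siblings were testable).
#' @export
branch_ks_decision <- function(samples, alpha = 0.05, min_count = 5) {
  stopifnot(is.list(samples), length(samples) >= 1L, !is.null(names(samples)))
  testable <- names(samples)[vapply(samples, length, integer(1)) >= min_count]
  tests <- data.frame(sibling_1 = character(0), sibling_2 = character(0),
                      statistic = numeric(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(testable) < 2L) {
    return(list(decision = "retain", tests = tests, tested = testable,
                flagged = TRUE))
  }
  pairs <- utils::combn(testable, 2L)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]
    b <- pairs[2L, k]
    kt <- suppressWarnings(stats::ks.test(samples[[a]], samples[[b]]))
    tests[nrow(tests) + 1L, ] <- list(a, b, unname(kt$statistic),
                                      unname(kt$p.value))
  }
  decision <- if (any(tests$p_value < alpha)) "reject" else "retain"
  list(decision = decision, tests = tests, tested = testable, flagged = FALSE)
}

#' Estimate a context tree from a response-time series
#'
#' Extension of Rissanen's Context algorithm to a symbol sequence paired
#' with real-valued responses. A queue `C` is initialised with every
#' length-`K` string occurring in the sample, sorted in reverse
#' lexicographic order. Repeatedly the first candidate `w` is taken and its
#' sibling family `F(w)` formed; if the whole family is pending, the
#' response-time distributions of the siblings are compared with pairwise
#' Kolmogorov-Smirnov tests — a rejection moves the family into the
#' estimated tree, a retention replaces the family by its common suffix at
#' the back of the queue; a singleton family is shortened without testing;
#' and a family only partially pending has its pending part moved into the
#' tree. The loop ends when the queue is empty. If pruning reaches the
#' root everywhere, the root-only (memoryless) tree is returned.
#'
#' @param kicks Integer symbol sequence.
#' @param response_times Aligned numeric response times.
#' @param K Maximum candidate depth (default 3).
#' @param alpha Level of each Kolmogorov-Smirnov test (default 0.05).
#' @param min_count Minimum per-sibling sample size for testing (default 5).
#' @param alphabet Alphabet, default `0:2`.
#' @return A `context_tree`; attribute `"branch_tests"` records every
#'   family decision (labels, D statistics, p-values) and attribute
#'   `"parameters"` the settings used.
#' @examples
#' cfg <- cohort_config(n_participants = 1, n_trials = 400)
#' s <- generate_session(cfg, seed = 7)
#' estimate_context_tree(s$kicks, s$response_times)
#' @export
estimate_context_tree <- function(kicks, response_times, K = 3, alpha = 0.05,
                                  min_count = 5, alphabet = 0:2) {
  if (!is.numeric(K) || K < 1) stop("K must be at least 1")
  K <- as.integer(K)
  stopifnot(length(kicks) == length(response_times))
  if (length(kicks) <= K) {
    warning("sequence no longer than K; returning the root-only tree")
    return(structure(context_tree("", alphabet),
                     branch_tests = list(),
                     parameters = list(K = K, alpha = alpha,
                                       min_count = min_count)))
  }
  if (length(unique(response_times)) == 1L) {
    warning("response times are constant; no branch can be rejected and ",
            "the estimated tree will be shallow")
  }
  C <- reverse_lex_sort(occurring_strings(kicks, K))
  tau <- character(0)
  log <- list()
  sample_cache <- new.env(parent = emptyenv())
  get_sample <- function(lab) {
    if (!exists(lab, envir = sample_cache, inherits = FALSE)) {
      assign(lab, collect_context_rt_samples(kicks, response_times, lab),
             envir = sample_cache)
    }
    get(lab, envir = sample_cache, inherits = FALSE)
  }
  while (length(C)) {
    w <- C[1L]
    if (!nzchar(w)) {       # the empty suffix cannot be split further
      C <- C[-1L]
      next
    }
    Fw <- sibling_family(kicks, w, alphabet)
    if (length(Fw) == 1L && Fw == w) {
      C <- C[C != w]
      suf <- substring(w, 2L)
      if (!(suf %in% C)) C <- c(C, suf)
    } else if (all(Fw %in% C)) {
      samples <- stats::setNames(lapply(Fw, get_sample), Fw)
      dec <- branch_ks_decision(samples, alpha = alpha, min_count = min_count)
      log[[length(log) + 1L]] <- c(list(family = Fw), dec)
      if (dec$decision == "reject") {
        tau <- c(tau, Fw)
        C <- C[!(C %in% Fw)]
      } else {
        C <- C[!(C %in% Fw)]
        suf <- substring(w, 2L)
        if (!(suf %in% C)) C <- c(C, suf)
      }
    } else {
      pending <- intersect(Fw, C)
      tau <- c(tau, pending)
      C <- C[!(C %in% pending)]
    }
  }
  if (!length(tau)) tau <- ""
  structure(context_tree(tau, alphabet),
            branch_tests = log,
            parameters = list(K = K, alpha = alpha, min_count = min_count))
}

#' Estimate context trees per epoch
#'
#' Splits the session at the rest-interval positions and estimates a
#' context tree independently on each epoch's trial range.
#'
#' @param session A [session_data()] object.
#' @param boundaries Last trials of the non-final epochs
#'   (default `c(334, 668)`).
#' @param K,alpha,min_count Passed to [estimate_context_tree()].
#' @return Named list of `context_tree` objects (`"epoch_1"`, ...); epochs
#'   shorter than `K + 1` trials are skipped with a warning.
#' @export
estimate_by_epoch <- function(session, boundaries = c(334, 668), K = 3,
                              alpha = 0.05, min_count = 5) {
  stopifnot(inherits(session, "session_data"))
  epochs <- split_epochs(length(session$kicks), boundaries)
  out <- list()
  for (i in seq_len(nrow(epochs))) {
    idx <- seq.int(epochs$start[i], epochs$end[i])
    if (length(idx) < K + 1L) {
      warning("epoch ", i, " has fewer than K + 1 trials; skipped")
      next
    }
    out[[paste0("epoch_", i)]] <-
      estimate_context_tree(session$kicks[idx], session$response_times[idx],
                            K = K, alpha = alpha, min_count = min_count,
                            alphabet = session$alphabet)
  }
  out
}

#' Mode context tree across participants
#'
#' Counts, for every context appearing in any estimated tree, the number of
#' trees containing it, and retains the contexts present in at least a
#' `threshold` fraction of trees. Suffix conflicts among retained contexts
#' are resolved by keeping the more frequent member (ties favour the longer
#' context).
#'
#' @param trees Non-empty list of `context_tree` objects.
#' @param threshold Retention fraction in `[0, 1]` (default 0.5).
#' @return A list of class `mode_tree_result` with elements `counts`
#'   (tibble: context, n_trees, fraction), `threshold`, `n_trees` and
#'   `tree` (the resulting `context_tree`).
#' @export
mode_context_tree <- function(trees, threshold = 0.5) {
  if (!is.list(trees) || !length(trees)) {
    stop("mode_context_tree() needs at least one estimated tree")
  }
  stopifnot(all(vapply(trees, inherits, logical(1), "context_tree")))
  n <- length(trees)
  all_ctx <- unlist(lapply(trees, `[[`, "contexts"))
  counts <- table(all_ctx)
  tab <- tibble::tibble(context = names(counts),
                        n_trees = as.integer(counts),
                        fraction = as.integer(counts) / n)
  tab <- tab[order(-tab$n_trees, -nchar(tab$context), tab$context), ]
  retained <- tab$context[tab$fraction >= threshold]
  # resolve suffix conflicts: more frequent wins, ties go to the longer
  keep <- retained
  repeat {
    conflict <- FALSE
    for (u in keep) {
      for (v in keep) {
        if (u == v) next
        u_is_suffix <- nchar(u) < nchar(v) &&
          (u == "" || substring(v, nchar(v) - nchar(u) + 1L) == u)
        if (u_is_suffix) {
          cu <- tab$n_trees[tab$context == u]
          cv <- tab$n_trees[tab$context == v]
          drop <- if (cu > cv) v else u   # tie -> keep the longer (v)
          keep <- keep[keep != drop]
          conflict <- TRUE
          break
        }
      }
      if (conflict) break
    }
    if (!conflict) break
  }
  alphabet <- trees[[1L]]$alphabet
  structure(list(counts = tab, threshold = threshold, n_trees = n,
                 tree = context_tree(if (length(keep)) keep else "", alphabet)),
            class = "mode_tree_result")
}

#' @export
print.mode_tree_result <- function(x, ...) {
  cat("Mode context tree over", x$n_trees, "estimated trees (threshold",
      x$threshold, "):\n")
  print(x$tree)
  cat("Per-context counts:\n")
  print(as.data.frame(x$counts), row.names = FALSE)
  invisible(x)
}
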