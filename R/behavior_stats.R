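#' Split a trial range into epochs
#'
#' @param n_trials Total number of trials.
#' @param boundaries Last trials of the non-final epochs, strictly
#'   increasing and `< n_trials`; `c(334, 668)` reproduces the protocol's
#'   rest positions for a 1000-trial session. An empty vector yields a
#'   single epoch.
#' @return A data frame with columns `epoch`, `start`, `end` (closed,
#'   1-based ranges partitioning `1..n_trials`).
#' @examples
#' split_epochs(1000, c(334, 668))
#' @export
split_epochs <- function(n_trials, boundaries = c(334, 668)) {
  stopifnot(is.numeric(n_trials), length(n_trials) == 1L, n_trials >= 1)
  boundaries <- as.integer(boundaries)
  if (length(boundaries)) {
    if (is.unsorted(boundaries, strictly = TRUE) || any(boundaries < 1) ||
        any(boundaries >= n_trials)) {
      stop("epoch boundaries must be strictly increasing, >= 1 and < n_trials")
    }
  }
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, as.integer(n_trials))
  data.frame(epoch = seq_along(starts), start = starts, end = ends)
}

#' Correct and incorrect transition counts for a context
#'
#' Counts occurrences of `w` ending at step `n` (excluding the final trial)
#' with `X_{n+1} = a`, split into correctly predicted (`Y_{n+1} = a`) and
#' incorrectly predicted (`Y_{n+1} != a`) transitions.
#'
#' @param kicks,predictions Aligned integer sequences.
#' @param w Context (non-empty).
#' @param a Target symbol.
#' @return A list of class `transition_counts` with fields `context`,
#'   `target`, `n_correct`, `n_incorrect`, and the occurrence step vectors
#'   `steps_correct`, `steps_incorrect`.
#' @export
transition_counts <- function(kicks, predictions, w, a) {
  stopifnot(length(kicks) == length(predictions))
  a <- as.integer(a)
  ends <- occurrence_ends(kicks, w)
  ends <- ends[ends < length(kicks)]
  ends <- ends[kicks[ends + 1L] == a]
  correct <- predictions[ends + 1L] == a
  structure(list(context = context_label(w), target = a,
                 n_correct = sum(correct), n_incorrect = sum(!correct),
                 steps_correct = ends[correct],
                 steps_incorrect = ends[!correct]),
            class = "transition_counts")
}

#' Index of correctly predicted transitions
#'
#' The fraction of occurrences of the transition `w -> a` that the
#' participant predicted correctly:
#' `I = N_correct / (N_correct + N_incorrect)`.
#'
#' @param counts A [transition_counts()] result.
#' @return A number in `[0, 1]`.
#' @export
correct_transition_index <- function(counts) {
  stopifnot(inherits(counts, "transition_counts"))
  total <- counts$n_correct + counts$n_incorrect
  if (total < 1L) {
    stop("transition ", counts$context, " -> ", counts$target,
         " never occurs; the index is undefined")
  }
  counts$n_correct / total
}

#' Trimmed mean
#'
#' Drops `floor(trim * n)` smallest and largest observations and averages
#' the remainder (delegating to `base::mean`'s `trim` argument).
#'
#' @param x Non-empty numeric sample.
#' @param trim Fraction in `[0, 0.5)` trimmed from each tail (default 0.2).
#' @return The trimmed mean.
#' @examples
#' trimmed_mean(c(1, 2, 3, 4, 100), trim = 0.2) # 3
#' @export
trimmed_mean <- function(x, trim = 0.2) {
  if (!length(x)) stop("cannot take the trimmed mean of an empty sample")
  if (!is.numeric(trim) || length(trim) != 1L || trim < 0 || trim >= 0.5) {
    stop("trim must lie in [0, 0.5)")
  }
  if (length(x) - 2L * floor(length(x) * trim) < 1L) {
    stop("trimming removes every observation")
  }
  mean(x, trim = trim)
}

#' Split a context's response times by the last context-0 prediction outcome
#'
#' For each occurrence of `w` ending at step `n` (with `T_{n+1}` defined),
#' the most recent strictly-prior context-0 transition is located:
#' `m* = max(m : X_m = 0, m + 1 <= n)`. The response time `T_{n+1}` joins
#' the success sample when the prediction at step `m* + 1` was correct
#' (`Y_{m*+1} = X_{m*+1}`) and the failure sample otherwise. Occurrences
#' with no prior context-0 transition are discarded. For `w = "0"` itself
#' the rule conditions on the previous triplet's 0, one step forward for
#' `"2"`, two for `"21"`.
#'
#' @param kicks,predictions,response_times Aligned sequences.
#' @param w Context (non-empty).
#' @param trim Trim fraction for the reported means (default 0.2).
#' @return A list of class `conditioned_rt` with the success and failure
#'   samples, their sizes, trimmed means, the paired difference
#'   (failure minus success; `NA` when either sample is empty) and the
#'   number of discarded occurrences.
#' @export
condition_rt_on_last_zero_outcome <- function(kicks, predictions,
                                              response_times, w, trim = 0.2) {
  n_total <- length(kicks)
  stopifnot(length(predictions) == n_total,
            length(response_times) == n_total)
  if (!any(kicks == 0L)) {
    warning("context 0 never occurs; conditioning is empty")
  }
  ends <- occurrence_ends(kicks, w)
  ends <- ends[ends < n_total]
  m_star_all <- last_zero_before(kicks)          # indexed by trial t = n + 1
  m_star <- m_star_all[ends + 1L]
  keep <- !is.na(m_star)
  ends_kept <- ends[keep]
  m_kept <- m_star[keep]
  success <- predictions[m_kept + 1L] == kicks[m_kept + 1L]
  t_succ <- response_times[ends_kept[success] + 1L]
  t_fail <- response_times[ends_kept[!success] + 1L]
  mean_s <- if (length(t_succ)) trimmed_mean(t_succ, trim) else NA_real_
  mean_f <- if (length(t_fail)) trimmed_mean(t_fail, trim) else NA_real_
  structure(list(context = context_label(w),
                 success = t_succ, failure = t_fail,
                 n_success = length(t_succ), n_failure = length(t_fail),
                 trim = trim, mean_success = mean_s, mean_failure = mean_f,
                 difference = mean_f - mean_s,
                 n_discarded = sum(!keep)),
            class = "conditioned_rt")
}

#' @export
print.conditioned_rt <- function(x, ...) {
  cat("Context ", x$context, ": ", x$n_success, " successes / ",
      x$n_failure, " failures (", x$n_discarded, " discarded)\n",
      "trimmed means (trim = ", x$trim, "): success ",
      signif(x$mean_success, 4), " s, failure ", signif(x$mean_failure, 4),
      " s, difference ", signif(x$difference, 4), " s\n", sep = "")
  invisible(x)
}

# exact null distribution of the (doubled) positive signed-rank sum, by
# convolution over sign assignments
signed_rank_pmf <- function(double_ranks) {
  total <- sum(double_ranks)
  pmf <- numeric(total + 1L)
  pmf[1L] <- 1
  for (s in double_ranks) {
    shifted <- c(rep(0, s), pmf[seq_len(total + 1L - s)])
    pmf <- (pmf + shifted) / 2
  }
  pmf   # pmf[k + 1] = P(2 * W+ = k)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped, absolute values are mid-ranked, and the
#' positive-rank sum `W+` is compared with its null distribution. The
#' reported statistic is the signed `Z` from the tie-corrected normal
#' approximation (positive when positive differences dominate). The
#' two-sided p-value is exact — computed from the full sign-flip
#' distribution, which handles ties — when `n <= exact_limit`, and taken
#' from the normal approximation otherwise.
#'
#' @param differences Numeric vector of paired differences.
#' @param exact_limit Use the exact distribution up to this many nonzero
#'   differences (default 50).
#' @return A list of class `rt_test` with `statistic` (Z), `w_plus`, `n`,
#'   `p_value`, `exact` and `method`.
#' @examples
#' wilcoxon_signed_rank(1:6)   # all positive: two-sided exact p = 0.03125
#' @export
wilcoxon_signed_rank <- function(differences, exact_limit = 50) {
  d <- differences[differences != 0]
  n <- length(d)
  if (!n) stop("all differences are zero; the test is degenerate")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sigma2 > 0) (w_plus - mu) / sqrt(sigma2) else 0
  exact <- n <= exact_limit
  if (exact) {
    pmf <- signed_rank_pmf(as.integer(round(2 * r)))
    k <- as.integer(round(2 * w_plus))
    p_ge <- sum(pmf[(k + 1L):length(pmf)])
    p_le <- sum(pmf[seq_len(k + 1L)])
    p <- min(1, 2 * min(p_ge, p_le))
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(statistic = z, w_plus = w_plus, n = n, p_value = p,
                 exact = exact,
                 method = "Wilcoxon signed-rank (two-sided)"),
            class = "rt_test")
}

#' Benjamini-Hochberg step-up procedure
#'
#' Orders the p-values ascending, finds the largest rank `k` with
#' `p_(k) <= q * k / M`, and rejects the `k` hypotheses with the smallest
#' p-values.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q Target false discovery rate in `(0, 1)` (default 0.05).
#' @return A list of class `bh_result` with `p_values`, `q`, `M`, `order`
#'   (ascending order permutation), `k` (cutoff rank, 0 when nothing is
#'   rejected) and `rejected` (logical, aligned with the input order).
#' @examples
#' benjamini_hochberg(c(0.01, 0.2, 0.02), q = 0.05)$rejected
#' @export
benjamini_hochberg <- function(p_values, q = 0.05) {
  stopifnot(is.numeric(p_values), all(p_values >= 0 & p_values <= 1),
            is.numeric(q), length(q) == 1L, q > 0, q < 1)
  M <- length(p_values)
  ord <- order(p_values)
  sorted <- p_values[ord]
  ok <- which(sorted <= q * seq_len(M) / M)
  k <- if (length(ok)) max(ok) else 0L
  rejected <- logical(M)
  if (k > 0L) rejected[ord[seq_len(k)]] <- TRUE
  structure(list(p_values = p_values, q = q, M = M, order = ord, k = k,
                 rejected = rejected),
            class = "bh_result")
}

#' Kruskal-Wallis rank test across groups
#'
#' Thin wrapper around [stats::kruskal.test()] (tie-corrected H statistic,
#' chi-squared reference with `groups - 1` degrees of freedom) with a guard
#' for all-constant data, where the tie correction degenerates and the test
#' is reported as `H = 0`, `p = 1`. The intended grouping in this package
#' is the predicted direction symbol, i.e. the response finger
#' (0 = index, 1 = middle, 2 = ring).
#'
#' @param samples Named list (at least two entries) of numeric samples.
#' @return A list of class `rt_test` with `statistic` (H), `df`, `p_value`
#'   and group sizes.
#' @export
kruskal_wallis_by_group <- function(samples) {
  stopifnot(is.list(samples))
  if (length(samples) < 2L) stop("at least two groups are required")
  if (any(lengths(samples) < 1L)) stop("every group needs an observation")
  x <- unlist(samples, use.names = FALSE)
  g <- factor(rep(names(samples), lengths(samples)))
  if (length(unique(x)) == 1L) {
    res <- list(statistic = 0, df = length(samples) - 1L, p_value = 1)
  } else {
    kt <- stats::kruskal.test(x, g)
    res <- list(statistic = unname(kt$statistic),
                df = unname(kt$parameter), p_value = kt$p.value)
  }
  structure(c(res, list(n = lengths(samples),
                        method = "Kruskal-Wallis rank sum")),
            class = "rt_test")
}

#' Kruskal-Wallis comparison of response times across fingers
#'
#' Groups a session's response times by the predicted direction symbol
#' (the finger used to respond) and applies [kruskal_wallis_by_group()].
#'
#' @param session A [session_data()] object.
#' @return An `rt_test` result.
#' @export
kruskal_wallis_by_finger <- function(session) {
  stopifnot(inherits(session, "session_data"))
  groups <- split(session$response_times, session$predictions)
  kruskal_wallis_by_group(groups)
}

#' @export
print.rt_test <- function(x, ...) {
  cat(x$method, ": statistic = ", signif(x$statistic, 4), sep = "")
  if (!is.null(x$df)) cat(", df =", x$df)
  cat(", p =", signif(x$p_value, 4), "\n")
  invisible(x)
}

#' Cohort-level misprediction analysis
#'
#' For every requested context and participant, response times are split by
#' the outcome of the prediction at the most recent context-0 transition
#' and the trimmed-mean difference (failure minus success) is computed.
#' Per context, the per-participant differences are tested against zero
#' with a two-tailed Wilcoxon signed-rank test, and the family of
#' per-context p-values is screened with the Benjamini-Hochberg procedure
#' at rate `q`.
#'
#' @param cohort List of at least two [session_data()] objects.
#' @param contexts Character vector of context labels to analyse.
#' @param trim Trim fraction for the per-participant means (default 0.2).
#' @param q False discovery rate for the Benjamini-Hochberg screen
#'   (default 0.05).
#' @param min_n Minimum size of both conditioned samples for a participant
#'   to enter a context's test (default 5).
#' @return A list of class `misprediction_analysis` with `summary`
#'   (tibble: context, n_participants, median_diff, Z, p, bh_rejected) and
#'   `participant_means` (tibble of per-participant conditioned means and
#'   differences), plus the settings used.
#' @export
run_misprediction_analysis <- function(cohort,
                                       contexts = c("0", "2", "01", "11", "21"),
                                       trim = 0.2, q = 0.05, min_n = 5) {
  stopifnot(is.list(cohort), length(cohort) >= 2L,
            all(vapply(cohort, inherits, logical(1), "session_data")))
  rows <- list()
  for (s in cohort) {
    for (w in contexts) {
      cr <- condition_rt_on_last_zero_outcome(s$kicks, s$predictions,
                                              s$response_times, w, trim)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant = s$participant_id, context = w,
        n_success = cr$n_success, n_failure = cr$n_failure,
        mean_success = cr$mean_success, mean_failure = cr$mean_failure,
        difference = cr$difference,
        included = cr$n_success >= min_n && cr$n_failure >= min_n)
    }
  }
  per_participant <- do.call(rbind, rows)
  summary_rows <- lapply(contexts, function(w) {
    sub <- per_participant[per_participant$context == w &
                             per_participant$included, ]
    if (nrow(sub) < 2L || all(sub$difference == 0)) {
      return(tibble::tibble(context = w, n_participants = nrow(sub),
                            median_diff = NA_real_, Z = NA_real_,
                            p = NA_real_))
    }
    test <- wilcoxon_signed_rank(sub$difference)
    tibble::tibble(context = w, n_participants = nrow(sub),
                   median_diff = stats::median(sub$difference),
                   Z = test$statistic, p = test$p_value)
  })
  summary <- do.call(rbind, summary_rows)
  testable <- !is.na(summary$p)
  summary$bh_rejected <- FALSE
  if (any(testable)) {
    bh <- benjamini_hochberg(summary$p[testable], q = q)
    summary$bh_rejected[testable] <- bh$rejected
  }
  structure(list(summary = summary, participant_means = per_participant,
                 trim = trim, q = q, min_n = min_n),
            class = "misprediction_analysis")
}

#' @export
print.misprediction_analysis <- function(x, ...) {
  cat("Misprediction analysis (trim = ", x$trim, ", q = ", x$q, "):\n",
      sep = "")
  print(as.data.frame(x$summary), row.names = FALSE, digits = 4)
  invisible(x)
}
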