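test_that("epoch splitting reproduces the protocol's trial ranges", {
  ep <- split_epochs(1000, c(334, 668))
  expect_identical(ep$start, c(1L, 335L, 669L))
  expect_identical(ep$end, c(334L, 668L, 1000L))
  single <- split_epochs(10, integer(0))
  expect_identical(c(single$start, single$end), c(1L, 10L))
  expect_error(split_epochs(10, 10), "< n_trials")
  expect_error(split_epochs(10, c(5, 3)), "strictly increasing")
})

test_that("transition counts split occurrences by prediction correctness", {
  y <- nine_predictions()          # all correct
  tc <- transition_counts(nine_kicks, y, "0", 2)
  expect_identical(tc$n_correct, 2L)
  expect_identical(tc$n_incorrect, 0L)
  expect_identical(tc$steps_correct, c(1L, 7L))

  y_wrong5 <- nine_predictions(correct = replace(rep(TRUE, 9), 5, FALSE))
  tc2 <- transition_counts(nine_kicks, y_wrong5, "0", 1)
  expect_identical(tc2$n_correct, 0L)
  expect_identical(tc2$n_incorrect, 1L)

  empty <- transition_counts(nine_kicks, y, "22", 1)
  expect_identical(empty$n_correct + empty$n_incorrect, 0L)
})

test_that("the index of correctly predicted transitions is the simple ratio", {
  fake <- structure(list(context = "0", target = 2, n_correct = 7L,
                         n_incorrect = 3L), class = "transition_counts")
  expect_equal(correct_transition_index(fake), 0.7)
  fake$n_correct <- 0L; fake$n_incorrect <- 5L
  expect_equal(correct_transition_index(fake), 0)
  fake$n_correct <- 2L; fake$n_incorrect <- 0L
  expect_equal(correct_transition_index(fake), 1)
  fake$n_correct <- 0L
  expect_error(correct_transition_index(fake), "undefined")
})

test_that("index is invariant under permutation of occurrence order", {
  set.seed(55)
  x <- generate_kicks(penalty_taker_tree(), 600, seed = 3)
  y <- generate_predictions(x, behavior_model(), seed = 4)
  tc <- transition_counts(x, y, "0", 2)
  idx <- correct_transition_index(tc)
  # shuffling whole (kick, prediction) trial pairs inside occurrence slots
  # cannot change the counts, only their order
  expect_equal(idx, tc$n_correct / (tc$n_correct + tc$n_incorrect))
  expect_identical(length(tc$steps_correct), tc$n_correct)
  expect_true(!is.unsorted(tc$steps_correct, strictly = TRUE))
})

test_that("rt conditioning follows the last context-0 prediction", {
  rts <- as.numeric(1:9) / 10
  # occurrence of 2 at n = 2: conditions on the prediction at trial 2
  y <- nine_predictions(correct = replace(rep(TRUE, 9), 8, FALSE))
  cr2 <- condition_rt_on_last_zero_outcome(nine_kicks, y, rts, "2", trim = 0)
  expect_equal(cr2$success, 0.3)   # T_3 after correct Y_2
  expect_equal(cr2$failure, 0.9)   # T_9 after incorrect Y_8
  # occurrence of 01 at n = 5: conditions on trial 5 (m* = 4)
  y5 <- nine_predictions(correct = replace(rep(TRUE, 9), 5, FALSE))
  cr01 <- condition_rt_on_last_zero_outcome(nine_kicks, y5, rts, "01",
                                            trim = 0)
  expect_equal(cr01$failure, 0.6)  # T_6 lands in the failure sample
  # occurrence of 0 at n = 4 conditions on the previous triplet's 0 (m* = 1)
  y2 <- nine_predictions(correct = replace(rep(TRUE, 9), 2, FALSE))
  cr0 <- condition_rt_on_last_zero_outcome(nine_kicks, y2, rts, "0", trim = 0)
  expect_equal(cr0$failure, 0.5)          # T_5 via failed Y_2
  expect_equal(cr0$success, 0.8)          # T_8 via correct Y_5
  expect_identical(cr0$n_discarded, 1L)   # the first 0 has no prior 0
})

test_that("conditioning partitions the counted occurrences", {
  x <- generate_kicks(penalty_taker_tree(), 800, seed = 10)
  y <- generate_predictions(x, behavior_model(), seed = 11)
  t <- as.numeric(generate_response_times(x, y, rt_model(), seed = 12))
  for (w in c("0", "2", "01", "11", "21")) {
    cr <- condition_rt_on_last_zero_outcome(x, y, t, w)
    ends <- occurrence_ends(x, w)
    counted <- sum(ends < length(x))
    expect_identical(cr$n_success + cr$n_failure + cr$n_discarded, counted)
  }
})

test_that("trimmed mean matches the sort-drop-average definition", {
  expect_equal(trimmed_mean(c(1, 2, 3, 4, 100), trim = 0.2), 3)
  expect_equal(trimmed_mean(c(2, 1, 3), trim = 0), 2)
  expect_equal(trimmed_mean(rep(5, 4), trim = 0.25), 5)
  set.seed(20)
  for (k in 1:50) {
    x <- stats::rlnorm(sample(1:40, 1))
    trim <- stats::runif(1, 0, 0.49)
    g <- floor(length(x) * trim)
    oracle <- if (length(x) - 2 * g >= 1) {
      mean(sort(x)[(g + 1):(length(x) - g)])
    } else {
      NA_real_
    }
    if (is.na(oracle)) {
      expect_error(trimmed_mean(x, trim))
    } else {
      expect_equal(trimmed_mean(x, trim), oracle)
    }
  }
  # approaches the median on odd samples as trim approaches one half
  x <- c(3, 9, 1, 40, 7)
  expect_equal(trimmed_mean(x, 0.49), stats::median(x))
  expect_error(trimmed_mean(numeric(0)), "empty")
  expect_error(trimmed_mean(1:3, trim = 0.5), "0.5")
})

test_that("wilcoxon signed-rank reproduces the exact sign-flip distribution", {
  res <- wilcoxon_signed_rank(1:6)
  expect_equal(res$p_value, 0.03125)
  expect_gt(res$statistic, 0)
  expect_equal(res$w_plus, 21)
  # antisymmetric differences: centred statistic, p = 1
  sym <- wilcoxon_signed_rank(c(1, -1, 2, -2))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)
  expect_error(wilcoxon_signed_rank(c(0, 0)), "degenerate")
})

test_that("wilcoxon exact p matches brute-force enumeration with ties", {
  enumerate_p <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- signs %*% r
    p_ge <- mean(w_all >= w_obs - 1e-9)
    p_le <- mean(w_all <= w_obs + 1e-9)
    min(1, 2 * min(p_ge, p_le))
  }
  set.seed(71)
  for (k in 1:25) {
    n <- sample(3:10, 1)
    d <- sample(c(-3, -2, -1, 1, 2, 3, 5), n, replace = TRUE)
    expect_equal(wilcoxon_signed_rank(d)$p_value, enumerate_p(d),
                 tolerance = 1e-12, label = paste(d, collapse = ","))
  }
})

test_that("wilcoxon agrees with stats::wilcox.test on tie-free data", {
  set.seed(14)
  for (k in 1:10) {
    d <- stats::rnorm(sample(5:12, 1))
    ours <- wilcoxon_signed_rank(d)
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$w_plus, unname(ref$statistic))
  }
})

test_that("benjamini-hochberg implements the step-up rule", {
  res <- benjamini_hochberg(c(0.01, 0.02, 0.2), q = 0.05)
  expect_identical(res$k, 2L)
  expect_identical(res$rejected, c(TRUE, TRUE, FALSE))
  expect_true(benjamini_hochberg(0.04, q = 0.05)$rejected)
  expect_identical(benjamini_hochberg(c(0.9, 0.95), q = 0.05)$k, 0L)
})

test_that("benjamini-hochberg matches p.adjust and is monotone in q", {
  set.seed(90)
  for (k in 1:30) {
    M <- sample(1:20, 1)
    p <- stats::runif(M)^sample(1:3, 1)   # skew some sets toward small p
    q <- stats::runif(1, 0.01, 0.2)
    res <- benjamini_hochberg(p, q)
    expect_identical(res$rejected,
                     stats::p.adjust(p, method = "BH") <= q,
                     info = sprintf("M=%d q=%.3f", M, q))
    wider <- benjamini_hochberg(p, min(0.99, q * 2))
    expect_true(all(wider$rejected | !res$rejected))
  }
})

test_that("kruskal-wallis H matches the brute-force rank formula", {
  oracle_h <- function(samples) {
    x <- unlist(samples)
    g <- rep(seq_along(samples), lengths(samples))
    r <- rank(x)
    N <- length(x)
    h <- 12 / (N * (N + 1)) *
      sum(tapply(r, g, sum)^2 / lengths(samples)) - 3 * (N + 1)
    ties <- table(x)
    h / (1 - sum(ties^3 - ties) / (N^3 - N))
  }
  blocks <- list(a = 1:10, b = 11:20, c = 21:30)
  expect_equal(kruskal_wallis_by_group(blocks)$statistic, oracle_h(blocks))
  set.seed(41)
  for (k in 1:20) {
    samples <- lapply(1:3, function(i) sample(1:8, sample(3:10, 1),
                                              replace = TRUE))
    names(samples) <- letters[1:3]
    expect_equal(kruskal_wallis_by_group(samples)$statistic,
                 oracle_h(samples), tolerance = 1e-12)
  }
  const <- kruskal_wallis_by_group(list(a = rep(2, 5), b = rep(2, 4)))
  expect_equal(const$statistic, 0)
  expect_equal(const$p_value, 1)
  expect_error(kruskal_wallis_by_group(list(a = 1:3)), "two groups")
})

test_that("kruskal-wallis p-values are calibrated under the null", {
  set.seed(300)
  pvals <- replicate(100, {
    samples <- split(stats::rnorm(90), rep(letters[1:3], 30))
    kruskal_wallis_by_group(samples)$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("misprediction analysis recovers directional shifts in a cohort", {
  cfg <- cohort_config(n_participants = 8, n_trials = 800,
                       epoch_boundaries = c(267, 534), seed = 15)
  cohort <- generate_cohort(cfg)
  res <- run_misprediction_analysis(cohort)
  s <- res$summary
  expect_gt(s$Z[s$context == "2"], 0)
  expect_lt(s$Z[s$context == "01"], 0)
  expect_true(s$bh_rejected[s$context == "2"])
  expect_true(s$bh_rejected[s$context == "01"])
  one <- run_misprediction_analysis(cohort, contexts = "2")
  expect_identical(nrow(one$summary), 1L)
  # per-participant table partitions cleanly
  expect_identical(nrow(res$participant_means), 8L * 5L)
})

test_that("finger grouping compares response times by predicted symbol", {
  cfg <- cohort_config(n_participants = 1, n_trials = 500,
                       epoch_boundaries = c(167, 334), seed = 23)
  s <- generate_session(cfg, seed = 24)
  res <- kruskal_wallis_by_finger(s)
  expect_equal(res$df, 2)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
})
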