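test_that("context response-time samples use the next trial's time", {
  expect_equal(collect_context_rt_samples(toy_kicks, toy_rts, "2"), 0.3)
  expect_equal(collect_context_rt_samples(toy_kicks, toy_rts, "0"),
               c(0.2, 0.5))
  # the only occurrence of 11 ends at the final trial: no next response
  expect_length(collect_context_rt_samples(toy_kicks, toy_rts, "11"), 0)
})

test_that("sibling families contain exactly the occurring one-symbol extensions", {
  x <- generate_kicks(penalty_taker_tree(), 500, seed = 31)
  fam11 <- sibling_family(x, "11")
  expect_true(all(fam11 %in% c("01", "11", "21")))
  expect_true(all(c("01", "11", "21") %in% fam11))  # all occur at n = 500
  # depth 1: the family is every occurring symbol
  expect_setequal(sibling_family(x, "2"), c("0", "1", "2"))
  expect_identical(sibling_family(c(0L, 0L, 0L, 0L), "00"), "00")
})

test_that("branch KS decisions follow the at-least-two-leaves rule", {
  disjoint <- list(a = runif(50, 0, 1), b = runif(50, 2, 3))
  dec <- branch_ks_decision(disjoint, alpha = 0.05)
  expect_identical(dec$decision, "reject")
  expect_equal(dec$tests$statistic, 1)
  same <- list(a = c(1, 2, 3, 4, 5, 6), b = c(1, 2, 3, 4, 5, 6))
  expect_identical(branch_ks_decision(same)$decision, "retain")
  trio <- list(a = runif(30), b = runif(30) + 5, tiny = runif(2))
  dec3 <- branch_ks_decision(trio, min_count = 5)
  expect_identical(nrow(dec3$tests), 1L)        # tiny sibling excluded
  expect_setequal(dec3$tested, c("a", "b"))
  under <- branch_ks_decision(list(a = runif(2), b = runif(2)), min_count = 5)
  expect_identical(under$decision, "retain")
  expect_true(under$flagged)
})

test_that("the estimator recovers the generating tree from separated rts", {
  cfg <- cohort_config(n_participants = 1, n_trials = 3000,
                       epoch_boundaries = c(1000, 2000), seed = 6)
  s <- generate_session(cfg, seed = 60)
  tau_hat <- estimate_context_tree(s$kicks, s$response_times, K = 3,
                                   alpha = 0.05)
  expect_true(same_tree(tau_hat, context_tree(c("0", "2", "01", "11", "21"))))
  # determinism
  tau_hat2 <- estimate_context_tree(s$kicks, s$response_times, K = 3,
                                    alpha = 0.05)
  expect_true(same_tree(tau_hat, tau_hat2))
  # decision metadata is recorded
  expect_gt(length(attr(tau_hat, "branch_tests")), 0)
})

test_that("context-independent rts yield shallow trees at small alpha", {
  shallow <- 0L
  for (seed in 1:15) {
    x <- generate_kicks(penalty_taker_tree(), 1000, seed = seed)
    t <- withr::with_seed(seed + 500, stats::rlnorm(1000, -0.5, 0.3))
    tau_hat <- estimate_context_tree(x, t, K = 3, alpha = 1e-9)
    if (tree_depth(tau_hat) <= 1L) shallow <- shallow + 1L
  }
  expect_gte(shallow, 14L)
})

test_that("spurious-depth rates shrink as alpha shrinks", {
  depth2_rate <- function(alpha) {
    hits <- 0L
    for (seed in 1:25) {
      x <- generate_kicks(penalty_taker_tree(), 800, seed = seed)
      t <- withr::with_seed(seed + 900, stats::rlnorm(800, 0, 0.3))
      if (tree_depth(estimate_context_tree(x, t, alpha = alpha)) >= 2L) {
        hits <- hits + 1L
      }
    }
    hits
  }
  rates <- vapply(c(0.05, 0.001), depth2_rate, integer(1))
  expect_lte(rates[2], rates[1])
})

test_that("degenerate inputs are handled without crashing", {
  expect_warning(tau <- estimate_context_tree(c(0L, 1L, 0L, 1L, 0L),
                                              rep(0.5, 5), K = 3),
                 "constant")
  expect_true(is_suffix_free(tau$contexts))
  expect_warning(tau2 <- estimate_context_tree(c(0L, 1L), c(0.1, 0.2), K = 3),
                 "root-only")
  expect_identical(tau2$contexts, "")
  expect_error(estimate_context_tree(toy_kicks, toy_rts, K = 0), "at least 1")
})

test_that("estimated trees are suffix-free on randomised inputs", {
  set.seed(2024)
  for (k in 1:200) {
    n <- sample(30:120, 1)
    x <- sample(0:2, n, replace = TRUE)
    t <- stats::rlnorm(n, sample(c(-1, 0, 1), 1), 0.4)
    tau_hat <- suppressWarnings(
      estimate_context_tree(x, t, K = sample(2:3, 1),
                            alpha = sample(c(0.05, 0.5), 1), min_count = 3))
    expect_true(is_suffix_free(tau_hat$contexts))
  }
})

test_that("epoch-wise estimation splits at the protocol's rest positions", {
  cfg <- cohort_config(n_participants = 1, seed = 8)
  s <- generate_session(cfg, seed = 80)
  trees <- estimate_by_epoch(s)
  expect_named(trees, c("epoch_1", "epoch_2", "epoch_3"))
  # a single epoch reproduces the full-session estimate
  full <- estimate_context_tree(s$kicks, s$response_times)
  single <- estimate_by_epoch(s, boundaries = integer(0))
  expect_true(same_tree(single$epoch_1, full))
  # epochs shorter than K + 1 are skipped with a warning
  short <- session_data(toy_kicks, toy_kicks, toy_rts)
  expect_warning(estimate_by_epoch(short, boundaries = 5, K = 3), "skipped")
})

test_that("mode trees count contexts across participants", {
  tau <- context_tree(c("0", "2", "01", "11", "21"))
  unanimous <- mode_context_tree(list(tau, tau, tau), threshold = 0.5)
  expect_true(same_tree(unanimous$tree, tau))
  expect_true(all(unanimous$counts$n_trees == 3L))

  mixed <- list(context_tree(c("0", "1", "2")), context_tree(c("0", "1", "2")),
                tau)
  mode_mixed <- mode_context_tree(mixed, threshold = 0.5)
  expect_true(same_tree(mode_mixed$tree, context_tree(c("0", "1", "2"))))

  strict <- mode_context_tree(mixed, threshold = 1.0)
  expect_setequal(strict$tree$contexts, c("0", "2"))  # present in all three

  expect_error(mode_context_tree(list()), "at least one")
})

test_that("mode-tree suffix conflicts keep the more frequent context", {
  t_deep <- context_tree(c("0", "2", "01", "11", "21"))
  t_flat <- context_tree(c("0", "1", "2"))
  # "1" in 2 of 3 trees, "01"/"11"/"21" in 1 of 3: flat wins at 0.5
  res <- mode_context_tree(list(t_flat, t_flat, t_deep), threshold = 1 / 3)
  expect_true(all(c("0", "2") %in% res$tree$contexts))
  expect_true("1" %in% res$tree$contexts)
  expect_false(any(c("01", "11", "21") %in% res$tree$contexts))
  expect_true(is_suffix_free(res$tree$contexts))
})
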