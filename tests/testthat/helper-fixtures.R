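# Shared fixtures: tiny hand-checkable sequences and fast model settings.

toy_kicks <- c(0L, 2L, 1L, 0L, 1L, 1L)
toy_rts <- seq(0.1, 0.6, by = 0.1)

# the nine-trial worked sequence used across the statistics tests
nine_kicks <- c(0L, 2L, 1L, 0L, 1L, 1L, 0L, 2L, 1L)

# predictions for nine_kicks with full control of correctness per trial
nine_predictions <- function(correct = rep(TRUE, 9)) {
  sapply(seq_along(nine_kicks), function(i) {
    if (correct[i]) nine_kicks[i] else (nine_kicks[i] + 1L) %% 3L
  })
}

# a small cohort configuration that keeps unit tests fast
small_config <- function(n_participants = 4, n_trials = 400, seed = 42,
                         ...) {
  cohort_config(n_participants = n_participants, n_trials = n_trials,
                epoch_boundaries = round(c(n_trials / 3, 2 * n_trials / 3)),
                seed = seed, ...)
}

# independent suffix check via reversed-string prefix comparison
oracle_suffix_free <- function(labels) {
  rev_labs <- vapply(strsplit(labels, "", fixed = TRUE),
                     function(d) paste(rev(d), collapse = ""), character(1))
  for (i in seq_along(rev_labs)) {
    for (j in seq_along(rev_labs)) {
      if (i != j && nchar(rev_labs[i]) < nchar(rev_labs[j]) &&
          startsWith(rev_labs[j], rev_labs[i])) {
        return(FALSE)
      }
    }
  }
  TRUE
}
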