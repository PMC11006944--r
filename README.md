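# rtctree

Context-tree estimation from response times in sequential prediction
tasks.

## The problem

A participant plays goalkeeper in a penalty-kick video game: at each of
1000 trials they predict the penalty taker's direction (0 = left, 1 =
centre, 2 = right) and their response time is recorded. The kick sequence
is generated by a stochastic chain with memory of variable length: the law
of the next symbol depends on a variable-length suffix of the past — its
*context* — and the set of contexts forms the leaves of a rooted tree
τ. The shipped generating model is a concatenation of triplets `0 * 1`
(`*` = 2 with probability 0.7, else 1), whose context tree is
{0, 2, 01, 11, 21}.

`rtctree` answers two questions about such sessions:

1. **Can τ be recovered from the response times alone?** The package
   implements an extension of Rissanen's Context algorithm to real-valued
   responses: candidate contexts of length K are enqueued in reverse
   lexicographic order and sibling families are pruned bottom-up unless a
   two-sample Kolmogorov–Smirnov test finds that at least two siblings'
   response-time distributions differ at level α. Per-epoch estimation
   (rest intervals after trials 334 and 668) and a *mode context tree*
   across participants summarise a cohort.
2. **Do response times also depend on the outcome of past predictions?**
   For each context w, response times are split by whether the prediction
   at the most recent context-0 transition succeeded or failed; the
   per-participant difference of 20%-trimmed means (failure − success) is
   tested across participants with a two-tailed Wilcoxon signed-rank test,
   and the per-context p-values are screened with the Benjamini–Hochberg
   procedure. The index of correctly predicted transitions
   I(w→a) = N_correct / (N_correct + N_incorrect) and a Kruskal–Wallis
   comparison of response times across fingers complete the analysis.

A synthetic-data module (`generate_cohort()`) simulates complete sessions
— kicks from the probabilistic context tree, predictions from a
per-context-accuracy goalkeeper model, log-normal response times with
context-dependent locations and failure shifts — so the whole pipeline is
testable without any experimental data.

## Worked example

```r
library(rtctree)

cfg <- cohort_config(n_participants = 22, n_trials = 1000, seed = 3)
cohort <- generate_cohort(cfg)

trees <- lapply(cohort, function(s)
  estimate_context_tree(s$kicks, s$response_times, K = 3, alpha = 0.05))
mode_context_tree(trees, threshold = 0.5)
#> Mode context tree over 22 estimated trees (threshold 0.5 ):
#> Context tree over alphabet {0,1,2} with 5 context(s):
#>   0, 2, 01, 11, 21
#> Per-context counts:
#>  context n_trees   fraction
#>       01      22 1.00000000
#>       11      22 1.00000000
#>       21      22 1.00000000
#>        2      22 1.00000000
#>        0      21 0.95454545
#>      110       1 0.04545455
#>      210       1 0.04545455
```

The mode tree equals the generating tree: every participant's tree kept
the depth-2 contexts, one participant lost context 0 to a spurious
depth-3 split, and the two stray contexts fall below the 50% threshold.

```r
run_misprediction_analysis(cohort)
#> Misprediction analysis (trim = 0.2, q = 0.05):
#>  context n_participants median_diff       Z         p bh_rejected
#>        0             22   -0.001712 -0.5357 6.102e-01       FALSE
#>        2             22    0.285074  4.1069 4.768e-07        TRUE
#>       01             22   -0.201991 -4.1069 4.768e-07        TRUE
#>       11             22    0.007658  1.5746 1.207e-01       FALSE
#>       21             22    0.058840  4.1069 4.768e-07        TRUE
```

`median_diff` is the across-participant median of the trimmed-mean
response-time differences (failure minus success, in seconds): responses
after a failed prediction are ~0.29 s slower in context 2 and ~0.06 s
slower in context 21 (the effect propagating two steps after the 0),
~0.20 s *faster* in context 01, and unchanged in the null contexts 0 and
11 — exactly the shifts the simulator injected, with the
Benjamini–Hochberg screen rejecting the three true effects only.

`run_pipeline(run_config(cfg), "out/")` runs
simulate → estimate-per-epoch → mode-tree → analyse end to end and writes
session CSVs, per-epoch tree JSONs, mode trees, the report TSV and a
manifest.

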