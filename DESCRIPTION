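Package: rtctree
Title: Context Tree Estimation from Response Times in Sequential
    Prediction Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing response times recorded while a
    participant predicts the successive symbols of a stochastic chain
    with memory of variable length. Provides probabilistic context
    trees and a simulator for complete prediction-game sessions
    (stimulus sequence, predictions, response times); an extension of
    Rissanen's Context algorithm that estimates the context tree of
    the generating chain from a response-time series by pruning
    sibling branches with two-sample Kolmogorov-Smirnov tests; epoch-wise
    estimation and mode-tree aggregation across participants; and the
    associated behavioural statistics: response-time conditioning on
    the outcome of the most recent prediction in the stochastic
    context, trimmed-mean paired differences, Wilcoxon signed-rank
    tests, Benjamini-Hochberg false-discovery-rate control, the index
    of correctly predicted transitions, and Kruskal-Wallis comparisons
    across response fingers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
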