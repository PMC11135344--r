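Package: ertni
Title: Ensemble Regression Trees with Surrogate Splits and Normalized
    Importance for Neuroimaging Biomarker Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts cognitive scores (MMSE, CDRSB, ADAS) from region-level
    neuroimaging biomarker tables with bagged/random-forest ensembles of
    regression trees grown with surrogate splits.  Per-feature importance is
    the sum of node-risk reductions over all primary and surrogate splits
    divided by the branch-node count; a repeated 90/10 train/test scheme
    yields MSE, correlation and importance distributions; the square-root,
    mean-one normalized importance (NI) statistic is compared against a
    permutation null (label-shuffled refits, threshold mean + 2 SD) to flag
    significant brain regions, rank them, and build cross-score consensus
    maps.  Includes a synthetic ADNI-like cohort generator with plantable
    region-score effects, and the cohort-level comparisons used alongside
    (one-way ANOVA from raw data or printed summaries, chi-squared tests,
    Tukey HSD at a configurable family-wise error rate).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
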