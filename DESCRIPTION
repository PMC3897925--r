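Package: selstab
Title: Stability-Aware Random-Forest and Random-Ferns Gene Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Feature-selection robustness toolkit for p >> n expression data.
    Provides Random Ferns and Random Forest per-gene importance sources
    (Gini decrease, raw and normalised out-of-bag permutation importance),
    four selection algorithms built on them (Boruta shadow-feature testing,
    shadow t-test selection, recursive feature elimination, and a regularised
    random forest), and bootstrap-based assessment machinery: a binomial
    self-consistency statistic with Holm-Bonferroni correction for the
    stability of selections across resamples, and post-selection error
    estimation with paired one-sided signed-rank comparison between methods.
    Includes a synthetic-data generator with planted relevant, redundant and
    noise genes for calibration and benchmarking.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    data.table,
    jsonlite,
    randomForest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
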