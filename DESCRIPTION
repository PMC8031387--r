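Package: rankridge
Title: Robust Rank-Based Ridge Regression with Stein-Type Shrinkage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Rank-based (Jaeckel dispersion) estimation for linear models with
    ridge regularization and Stein-type shrinkage, for multicollinear,
    outlier-contaminated and possibly high-dimensional (p > n) regression such
    as gene-expression prediction.  Provides Wilcoxon-score R-estimation, the
    rank ridge regression estimator, a ridge rank-based quadratic-form test of
    the global null beta = 0 with an exact-permutation-moment calibrated
    decision rule, a Stein-type shrinkage estimator with ridge parameter k and
    shrinkage parameter d, a generalized cross-validation criterion that
    selects (k, d) jointly, leave-one-out cross-validation and relative
    efficiency metrics, and a Monte-Carlo framework with collinear designs and
    one-sided non-central chi-squared contamination for size/power and
    efficiency studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
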