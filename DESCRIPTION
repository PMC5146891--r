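Package: cfbench
Title: Benchmarking User-Based Collaborative Filtering Against
    Imputation and Classification for Clinical Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating user-based collaborative filtering as a
    clinical outcome predictor against logistic regression and random
    forests paired with four imputation strategies (mean, k-nearest
    neighbour, random-forest proximity, and chained equations). Includes
    a synthetic clinical-table generator with controllable class
    imbalance, MCAR and MAR missingness injectors with cumulative
    severity levels, quantile-based discretization, a cosine-similarity
    neighbourhood predictor that treats the outcome as a rateable item,
    calibration metrics (Hosmer-Lemeshow, Brier including the
    out-of-bag-vote variant), and a repeated cross-validation harness
    with folds held fixed across missingness levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
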