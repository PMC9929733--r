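Package: nextbg
Title: Next Blood Glucose Prediction from Sparse Inpatient Point-of-Care
    Measurements
Version: 1.0.0
Authors@R:
    person("Analytics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for forecasting the next blood glucose measurement of
    hospitalized patients from point-of-care and serum glucose histories
    alone.  Provides a synthetic inpatient cohort generator with realistic
    reading cadence and glycemic-variability structure, the reading-level
    exclusion cascade used to prepare sparse glucose streams for time-series
    analysis (5-minute block deduplication, 90-minute adjacency exclusion,
    10-hour next-gap rule), a battery of moving-average, rolling-regression,
    recursive-regression and sample-and-hold predictors, trailing 24-hour
    coefficient-of-variation stratification, evaluation by squared Pearson
    correlation, RMSE, median absolute error and Clarke Error Grid analysis,
    and a cross-validated comparison of regression learners on the pooled
    predictor set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
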