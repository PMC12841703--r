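Package: preecv
Title: The PRE-ECV Score and Its Internal Validation Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the PRE-ECV score, an eight-variable additive points
    system (range 0-13) for predicting the success of external cephalic
    version at term, and provides the full internal-validation toolkit for
    point-based clinical prediction scores: the univariable logistic mapping
    from score to success probability, ROC discrimination with DeLong and
    bootstrap confidence intervals, logistic recalibration (calibration
    intercept and slope), decile calibration bins and LOESS-smoothed
    calibration curves, bootstrap optimism correction of performance metrics,
    decision-curve analysis, Youden-index cutoff selection, confusion-matrix
    metrics and score-strata success rates with Wilson confidence intervals.
    A deterministic 100-patient fixture cohort reconstructed from published
    marginal counts and a Gaussian-copula synthetic-cohort generator make
    every analysis exercisable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
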