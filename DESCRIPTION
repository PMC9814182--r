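Package: dailycart
Title: Multi-Level Classification Trees for Next-Day Risk Prediction from
    Daily-Diary Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting next-day binary outcomes (such as
    suicidal ideation) from intensive longitudinal daily-diary surveys.
    Implements person-specific cumulative-mean and deviation feature
    construction, a generalized linear mixed-effects model tree (GLMM
    tree) learner with unbiased split selection via score-based parameter
    instability tests and participant random intercepts, participant-
    blocked stratified repeated k-fold cross-validation with ROC-based
    cutoff selection, extraction of fitted trees as explicit decision
    rules, and a calibrated synthetic daily-diary generator for testing
    the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
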