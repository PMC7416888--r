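Package: bayestransfer
Title: Simulation and Analysis of Bayesian Transfer in Spatial Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulate-and-analyze pipeline for psychophysical studies of
    Bayesian cue-prior integration in a hidden-target ("octopus") localization
    task. Provides the generative task design (two Gaussian location priors,
    dot-cloud likelihoods rescaled to exact SD, moment-balanced trial runs,
    interleaved prior-only trials, catch scoring), a family of observer models
    (ideal Bayesian, Bayesian-transfer, internal-noise-only, look-up-table
    learner, fixed-weight), synthetic cohort generation, and the full analysis
    chain: outlier exclusion, response-vs-centroid weight regression, centroid
    estimator comparison by R-squared, internal-noise estimation from a control
    task, closed-form weight predictions for three observer models, model
    comparison by mean squared error, and transfer contrasts with bootstrap
    confidence intervals.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
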