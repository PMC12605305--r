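Package: sirvar
Title: Variance Estimation for Log Standardized Incidence Ratios in Provider Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing health-care provider performance with log
    standardized incidence ratios (Log-SIR) computed by indirect
    standardization from a random-intercept logistic regression model.
    Implements three estimators of the variance of each center's Log-SIR
    (an analytic delta-method formula with shared-random-effect covariance
    terms, a nonparametric bootstrap, and a Bayesian hierarchical model
    sampled by Markov chain Monte Carlo), a seeded synthetic cohort
    generator with a Monte Carlo ground-truth oracle for scoring the
    estimators by bias, variance and mean squared error, and funnel plots
    with false-discovery-rate control limits for classifying centers as
    low, average or high performing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    pracma,
    ggplot2,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
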