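Package: priorconf
Title: Bayesian Observer Modelling of Decisions and Confidence Under
    Informative Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative Bayesian observer model for dual-decision perceptual
    experiments in which the correctness of a first ("lead") decision
    deterministically sets the direction of a second ("target") stimulus, so
    that internal confidence in the lead decision acts as the prior for the
    target decision. Provides the observer model with separate
    prior-precision weighting parameters for choices (w_choice) and
    confidence (w_conf) and a confidence-bias parameter (b); a synthetic
    experiment generator with adaptive 2-down-1-up and 3-down-1-up
    staircases and counterbalanced Stronger-Lead/Stronger-Target conditions;
    psychometric calibration of internal noise and decision bias via
    Akaike-weighted psychometric function variants; individual and
    hierarchical Bayesian estimation of Flexible, Flat-Prior, Optimal and
    Equal model variants by adaptive Markov chain Monte Carlo; model
    comparison by leave-one-group-out cross-validation (expected log
    pointwise predictive density); and parameter- and model-recovery study
    drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
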