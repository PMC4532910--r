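Package: durbayes
Title: Bayesian Observer Models for Duration Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling two-alternative forced-choice (2AFC) duration
    judgments of dynamic visual stimuli. Generates the trial schedules of a
    three-experiment duration-discrimination design (600 ms reference against
    26 comparison durations between 100 and 1100 ms), fits lapse-augmented
    cumulative-Gaussian psychometric functions on log duration, and implements
    a factorial family of 24 Bayesian observer models crossing four
    cue-combination rules for simultaneously presented high- and low-temporal-
    frequency stimuli (weighting, optimal integration, selection, reliable
    stimulus) with memory decay of the first interval and three prior
    structures (flat, single learned prior, separate reference and comparison
    priors with order marginalization). Trial-level choice probabilities are
    computed by Gauss-Hermite quadrature with a numerically searched decision
    boundary; models are fitted by maximum likelihood and compared by
    stratified 12-fold cross-validated log-likelihood.
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
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
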