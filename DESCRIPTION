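Package: confdcm
Title: Dynamic Causal Modelling of Decision Confidence and Speed from ERPs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Effective-connectivity analysis of perceptual decision confidence
    and speed. Provides a canonical-microcircuit (CMC) neural mass forward
    model for event-related potentials, variational-Laplace model inversion
    with free-energy model evidence, group-level Bayesian model comparison
    (fixed and random effects, exceedance probabilities, Bayesian model
    averaging and reduction, parametric empirical Bayes), behavioral
    stratification of reaction times and confidence ratings, a trial-by-trial
    latent-state nonlinear encoding pipeline based on support vector
    regression with permutation importance and bootstrap thresholds, and a
    synthetic cohort generator that emulates the behavioral and neural
    statistics of a perceptual confidence experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
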