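Package: bcfselect
Title: Bayesian Causal Forests for Individualised Treatment Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Develops and validates individualised treatment selection models
    for two-arm therapy comparisons from routine clinical data, built around a
    from-scratch Bayesian causal forest: a probit tree-ensemble propensity
    model, an outcome model with separate prognostic and treatment-effect tree
    ensembles fitted by backfitting MCMC, and optional Dirichlet sparsity
    priors on split-variable probabilities. Includes a synthetic-cohort
    generator with confounded treatment assignment and known treatment-effect
    surfaces (modelled on people with type 2 diabetes initiating SGLT2
    inhibitors or GLP-1 receptor agonists), study eligibility filters,
    variable selection from splitting probabilities, best-linear-projection
    variable importance, benefit subgrouping, and a calibration validation
    framework comparing subgroup-average predicted conditional treatment
    effects against covariate-adjusted and propensity-matched average
    treatment effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    arrow,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
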