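Package: misslong
Title: Missing-Data Workflows for Longitudinal Immunology Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing small longitudinal immunophenotyping cohorts
    with substantial assay-level missingness. Provides a calibrated synthetic
    cohort generator (two antiretroviral-therapy arms plus exposed-uninfected
    controls, panel-structured MCAR/MAR/MNAR missingness), maximum-likelihood
    estimation for incomplete multivariate normal data by
    expectation-maximisation, Little's test of the missing-completely-at-random
    hypothesis, bootstrap-EM multiple imputation with overimputation
    diagnostics and Rubin's-rules pooling, a one-step full-Bayesian
    data-augmentation sampler under normal and Poisson likelihoods with
    Gelman-Rubin and DIC diagnostics, and cross-method concordance reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mvtnorm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    truncnorm,
    utils,
    withr
Suggests:
    broom,
    coda,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
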