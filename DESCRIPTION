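Package: stgpr
Title: Spatio-Temporal Gaussian Process Smoothing of Subnational Survey Prevalence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Small-area estimation of intervention coverage and disease
    prevalence from household-survey microdata. Computes design-weighted
    region-level proportions with Kish effective sample sizes, harmonises
    survey recall windows, and smooths the resulting empirical-logit
    observations with a Bayesian spatio-temporal Gaussian process whose
    covariance is a Kronecker product of a proper conditionally
    autoregressive (CAR) spatial correlation on a region adjacency graph
    and a first-order autoregressive temporal correlation, with
    heteroscedastic observation noise that shrinks as the log effective
    sample size grows. Fitting is by Metropolis-within-Gibbs MCMC with a
    joint Gaussian update of the latent field. Includes hold-out
    cross-validation, change and octile-ranking reports, a synthetic
    survey generator for end-to-end testing, and a config-driven pipeline
    runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
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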