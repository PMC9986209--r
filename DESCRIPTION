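Package: emadsem
Title: Dynamic Structural Equation Models for Momentary Stress-Affect Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing and Bayesian estimation for two-level
    dynamic structural equation models of ecological momentary assessment (EMA)
    data. Includes a synthetic-data generator emulating a 14-day smartphone
    EMA design with quasi-random prompts, equidistant time-gridding with
    explicit missing slots, sum-score and confirmatory factor measurement
    models for trait questionnaires, a conjugate Gibbs sampler for a latent
    vector-autoregressive model with trait-moderated person-specific dynamics,
    and reporting utilities for standardised estimates, credible intervals and
    indirect (mediation) effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
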