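Package: bhpr
Title: Bayesian Hierarchical Piecewise Regression for Trajectory Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Bayesian hierarchical piecewise (random change-point)
    regression models to long-format longitudinal data and detects the
    mechanism and age at which outcome trajectories diverge between groups
    of participants. Provides a Metropolis-within-Gibbs sampler with
    conjugate updates for linear fixed effects and variance components,
    adaptive random-walk updates for change points, missing-at-random
    imputation of time-varying covariates, DIC and posterior predictive
    model checks, a candidate-model suite spanning divergence mechanisms,
    the categorical mixed-model LS-means baseline with Tukey-adjusted
    pairwise contrasts, a generator for accelerated longitudinal designs,
    and a simulation-study driver comparing divergence-age estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    nlme,
    optparse,
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
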