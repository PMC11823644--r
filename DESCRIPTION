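Package: tobramap
Title: Two-Sample Log-Linear Regression Versus MAP Bayesian Estimation of
    Tobramycin Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-based comparison of the clinical-standard two-sample
    log-linear regression (LLR) estimator of tobramycin exposure with maximum
    a posteriori (MAP) Bayesian estimation under population pharmacokinetic
    priors. Provides analytic one- and two-compartment intravenous-infusion
    kinetics with covariate models, the LLR peak/trough grouping and fitting
    rules, MAP estimation with prior-weight flattening and M3 censored
    likelihood for concentrations below the limit of quantification, a
    virtual-patient simulator for adults with cystic fibrosis, predictive
    performance metrics (accuracy, MPE, nRMSE) with patient-level bootstrap
    intervals, and an orchestrated experiment pipeline over sampling designs
    and prior weights.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
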