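Package: cabopk
Title: Population Pharmacokinetic Modelling and Simulation of Cabozantinib
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Nonlinear mixed-effects population pharmacokinetic modelling of the
    tyrosine kinase inhibitor cabozantinib in healthy volunteers and cancer
    patients. Implements the closed-form two-compartment disposition model with
    dual (lagged first-order plus zero-order) oral absorption, power and
    fractional-change covariate models on clearance, central volume,
    absorption rate and bioavailability, log-normal inter-individual
    variability, and a log-additive residual error model. Provides forward
    simulation of virtual multi-study populations, marginal-likelihood
    estimation by the Laplace approximation with nested-model comparison,
    steady-state exposure metrics, goodness-of-fit and random-effect
    diagnostics, and posterior predictive checks via a smoothed parametric
    bootstrap.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    jsonlite
Config/testthat/edition: 3
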