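Package: dexbetpk
Title: Population Pharmacokinetics of Intramuscular and Oral
    Dexamethasone and Betamethasone
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Nonlinear mixed-effects analysis of dexamethasone (DEX) and
    betamethasone (BET) plasma concentrations after intramuscular and oral
    single doses. Implements a two-compartment disposition model with up to
    three first-order absorption depots (IM phosphate, oral, IM acetate) in
    closed form, log-normal inter-individual variability, a log-scale
    residual error model, Beal M3 handling of below-quantification data, and
    Laplace approximation of the marginal likelihood. Includes a synthetic
    crossover-study generator mirroring an 8-sequence, 48-subject design,
    model-based secondary descriptors (Cmax, tmax, AUC, terminal half-life,
    MRT), visual predictive checks, and simulation of WHO antenatal
    corticosteroid dosing regimens.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
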