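Package: phenotrial
Title: Phenomapping-Guided Adaptive Predictive Enrichment for Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for adaptive predictive enrichment
    of two-arm randomized clinical trials guided by computational trial
    phenomaps. At planned interim analyses the accrued population is split in
    half, a Gower-distance phenomap of the training half is built, per-patient
    individualized treatment-benefit estimates (log hazard ratios) are derived
    from phenotype-proximity-weighted Cox models, and a gradient-boosted tree
    regressor with Boruta shadow-feature selection links pre-randomization
    covariates to predicted benefit. When a prespecified interaction gate
    signals treatment-effect heterogeneity and revised power calculations
    permit a smaller trial, enrollment probability for subsequent candidates
    is conditioned on predicted benefit through a squared-sigmoid weight,
    within a group-sequential alpha-spending design. Includes a synthetic
    two-arm trial generator with known average and heterogeneous effects,
    leakage-free preprocessing (missingness and collinearity screens,
    winsorization, iterative forest imputation, one-hot encoding), win-ratio
    safety analyses, stability/concordance diagnostics, and an end-to-end
    experiment harness with a negative (covariate-shuffling) control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    survival,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    mvtnorm,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
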