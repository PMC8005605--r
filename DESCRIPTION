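Package: cefapk
Title: Population Pharmacokinetics and Dose Optimization of Cefathiamidine
    in Infants with Augmented Renal Clearance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A population pharmacokinetic analysis pipeline for intravenous
    cefathiamidine in infants with augmented renal clearance (ARC). Implements
    a one-compartment intermittent-infusion model with allometric weight
    scaling and an age power function on clearance, first-order conditional
    estimation with interaction (FOCE-I) of the nonlinear mixed-effects
    marginal likelihood, stepwise forward-selection/backward-deletion
    covariate screening, sampling importance resampling (SIR) parameter
    uncertainty analysis, normalized prediction distribution error (NPDE)
    model validation, and Monte Carlo probability-of-target-attainment (PTA)
    simulations of free time-above-MIC dosing targets. A synthetic-trial
    generator reproduces the covariate distributions and sparse opportunistic
    sampling design of an ARC infant cohort so that every stage of the
    pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
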