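Package: cytocoag
Title: Simulation of Cytokine-Enhanced Thrombin Generation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A mechanistic simulator of the interplay between
    pro-inflammatory cytokines (IL-6, IL-1beta, TNF-alpha) and the tissue
    factor initiated coagulation cascade. Provides a generic mass-action
    reaction-network engine with stiff ODE integration, a plasma-phase
    coagulation cascade model with perturbation scenarios, first-order
    cytokine kinetics calibrated from plasma half-lives, phenomenological
    Hill-type coupling laws for cytokine-driven tissue factor induction and
    anticoagulant suppression, a two-phase inflammation/coagulation
    scheduler with multi-cycle feedback amplification, thrombin-generation
    assay metrics (lag time, time-to-peak, peak, endogenous thrombin
    potential), Latin hypercube virtual-patient cohorts for disease-specific
    clinical ranges, and LHS-PRCC global sensitivity analysis with a dummy
    variable control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    jsonlite,
    yaml,
    lhs,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
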