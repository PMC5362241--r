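Package: rhozone
Title: Mechanochemical Simulation of Bistable RhoA Signaling Zones in a
    Contractile Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a one-dimensional mechanochemical model of junctional
    RhoA signaling in epithelia: a bistable RhoA-NMIIA positive-feedback
    circuit coupled to diffusion on the cell cortex and to advection by
    actomyosin flow.  The flow is obtained from a quasi-static force balance
    in which myosin-generated active stress, saturating in myosin
    concentration, drives motion against friction and viscosity.  Depending
    on the Peclet number the model produces travelling bistable fronts or a
    stationary localized signaling zone pinned by convergent flow.  Includes
    phase-plane analysis of the well-mixed kinetics (fixed points,
    nullclines, separatrix), parameter sweeps and bisection for the critical
    Peclet number, time-triggered perturbation protocols emulating
    contractility inhibition and washout, diagnostics of zone width, front
    speed, stationarity and clustering, and kymograph quantification of zone
    width and intensity for simulated or imaged data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
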