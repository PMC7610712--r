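Package: isostim
Title: Isostable and Hilbert Amplitude Fields for Closed-Loop Neurostimulation in Stochastic Wilson-Cowan Tremor Models
Version: 0.1.0
Authors@R:
    person("isostim", "developers", email = "isostim@example.org", role = c("aut", "cre"))
Description: A modelling workbench for closed-loop deep brain stimulation in
    two-dimensional stochastic Wilson-Cowan neural mass models of essential
    tremor. Provides deterministic and stochastic (Euler-Maruyama) integrators
    with pulse stimulation, fixed-point and stable-focus linearization
    analysis, isostable amplitude computation over phase-space grids,
    ensemble-averaged Hilbert amplitude fields, instantaneous and augmented
    amplitude-response fields, a phase-space stimulation controller with
    temporal discounting, phase-locked and open-loop high-frequency baselines,
    and power/energy based strategy evaluation. Ships a synthetic patient-like
    model generator so that the whole pipeline is testable without any
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
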