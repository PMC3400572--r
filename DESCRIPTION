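Package: dendarith
Title: Location-Dependent Synaptic Summation on Pyramidal-Neuron Basal Dendrites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how proximal and distal excitatory inputs to thin
    basal dendrites interact through NMDA-receptor nonlinearities. Provides a
    reduced compartmental cable simulator (passive membrane, Hodgkin-Huxley
    sodium/potassium currents, AMPA/NMDA synapses with voltage-dependent
    magnesium block), a time-invariant two-compartment circuit solver, the
    nonlinearity-relative-to-linear-extrapolation (NRLE) statistic and local
    spike-threshold detection for input-output curves, two-input summation
    mapping, fiducial-point normalization of heterogeneous curve families,
    firing-rate gain/threshold analysis under Poisson drive, EPSP time-course
    metrics, and a synthetic-cohort generator standing in for slice recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
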