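Package: thalamogate
Title: Population Stochastic Facilitation and Information Transfer in the
    Retino-Thalamo-Cortical Circuit
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of sensory information transfer across
    the thalamic gateway. Provides single-compartment Hodgkin-Huxley-type
    models of thalamocortical relay and layer-4 cortical neurons, gamma-process
    retinal spike generators, dual Ornstein-Uhlenbeck corticothalamic
    conductance bombardment with controllable excitation-inhibition and
    across-cell correlation, a fast event-driven network integrator, hybrid
    replay of pseudo-recorded thalamic layers, and a windowed binary-word
    mutual-information "transfer efficiency" estimator with bootstrap bias
    correction and finite-size diagnostics, together with a reproducible
    parametric experiment runner.
License: GPL-3
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
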