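Package: pecircuit
Title: Prediction-Error Microcircuits with Feature-Selective Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Firing-rate simulation of a cortical microcircuit that learns to
    compute prediction errors for one- and two-dimensional stimulus features.
    The network couples two-compartment pyramidal cells to PV, SOM (Martinotti
    and non-Martinotti) and VIP interneurons with Gaussian feature tuning, and
    trains the inhibitory synapses with gradient-derived plasticity rules that
    drive each somatic and dendritic compartment towards excitation-inhibition
    balance. Includes the full measurement layer: prediction-error neuron
    classification, the selectivity coefficient, similarity measures,
    tuning-curve refits, mismatch-scaling summaries, pathway excitation and
    inhibition decomposition via the grouped weight matrix, attention gain
    protocols, and reproducible end-to-end experiment runners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
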