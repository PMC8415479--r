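Package: ddtnet
Title: Double-Threshold Pruning of Functional Connectivity Matrices from
    Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to recover the structural topology of large-scale neuronal
    networks from functional connectivity matrices inferred from spike trains.
    Implements the adaptive Double-Threshold (DDT) pruning algorithm together
    with hard-threshold, density-based and shuffle-based reference methods, and
    a complete in-silico benchmark: random, small-world, scale-free and modular
    structural network generators with excitatory/inhibitory block structure,
    an Izhikevich spiking-network simulator with conduction delays and
    spike-timing-dependent plasticity, a signed delayed cross-correlation
    connectivity estimator, spike and burst statistics, topological metrics
    (small-world index, degree-distribution fits, hub detection) and
    three-class classification accuracy against the structural ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    minpack.lm,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    Matrix
Config/testthat/edition: 3
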