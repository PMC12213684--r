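Package: socnet
Title: Self-Organized Criticality in Spiking Neural Networks with Dynamical Synapses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates discrete-time stochastic leaky integrate-and-fire neural
    networks with a homeostatic synaptic increase/depression rule on five directed
    network topologies (regular ring, small-world, scale-free, modular, random),
    and provides the avalanche-analysis stack built around them: avalanche
    extraction from spike-count traces, critical-point estimation by the
    susceptibility peak under a synaptic-strength scan, discrete truncated
    power-law fitting of avalanche-size distributions, four-way dynamical-regime
    classification including Dragon-king detection, deviation indices of the
    network-mean synaptic strength from its critical value, inter-spike-interval
    and hub-activity metrics, and phase-diagram sweep drivers over plasticity
    timescales. Results are returned as tibbles with ggplot2 autoplot methods
    and broom-style tidiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
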