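Package: cxsim
Title: Spiking Ring-Attractor Models of the Drosophila Central Complex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale spiking-circuit simulator for comparing ring-attractor
    models of the fruit-fly central complex. Builds three published circuit
    architectures over protocerebral-bridge glomeruli and ellipsoid-body
    wedges as typed neuron/synapse graphs, integrates leaky integrate-and-fire
    neurons coupled by alpha, exponential (AMPA/GABA-A) and NMDA synapses with
    a deterministic fixed-step engine, renders moving-bar visual protocols
    through retinotopic receptive fields into injected currents or Poisson
    spike drives, supports neuron silencing/ablation experiments, and analyses
    the resulting activity bump (per-wedge mean firing rates, population-vector
    position, width, tracking error, persistence).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    igraph,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
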