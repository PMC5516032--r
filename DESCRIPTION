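Package: spikemem
Title: Flexible and Stable Memory in Feedforward Spiking Networks with
    Weight-Dependent STDP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates memory formation, decay and interference in a sparse
    feedforward network of leaky integrate-and-fire neurons whose synapses
    follow spike-timing-dependent plasticity (STDP) with weight-dependent
    learning rates.  Provides asymmetric (multiplicative), symmetric
    (mid-range-peaked) and hybrid learning-rate profiles, the synaptic
    instability functional and its Boltzmann stationary-density predictor,
    single-synapse Monte-Carlo validation, temporal input-pattern and
    Poisson spike-train generators, a memory-index statistic over binary
    response vectors, and complete experiment protocols (training/testing,
    noise-driven decay, sequential pattern appending, and sweeps over the
    hybrid mixing parameter) run over cohorts of seeded network instances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
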