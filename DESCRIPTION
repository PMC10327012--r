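Package: hippospike
Title: Data-Driven Spiking Neural Network Models of Hippocampal Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds and simulates biologically detailed spiking neural
    networks of the rodent hippocampal formation from neuron-type
    parameter tables: per-type census counts, nine-parameter Izhikevich
    neuron models, directed connection probabilities, and
    Tsodyks-Pawelzik-Markram short-term synaptic plasticity constants.
    Also estimates potential connectivity from axonal and dendritic
    lengths, inter-bouton distances, and parcel volumes; instantiates
    probabilistic connectomes; integrates hybrid neuron dynamics with
    conductance-based synapses; computes a local-field-potential proxy
    with theta, gamma, and ripple band decomposition; and classifies
    firing-pattern phenotypes from interspike-interval statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
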