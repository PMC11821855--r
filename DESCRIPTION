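Package: tastetrace
Title: Tracing and Modeling Taste Circuits in a Whole-Brain Connectome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for tracing gustatory pathways through a whole-brain
    synaptic connectome. Reads FlyWire-dialect neuron and connection tables,
    identifies second- and third-order taste neurons downstream of gustatory
    receptor neuron (GRN) seed sets under synapse-count thresholds, and
    quantifies cross-modality overlap, excitatory/inhibitory feedback and
    lateral motifs, subesophageal-zone and hemisphere output partitions, and
    input composition. Includes a leaky integrate-and-fire network simulator
    for predicting taste-evoked activity, and a synthetic-connectome
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
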