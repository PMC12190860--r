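Package: allonet
Title: Ensemble-Based Residue Interaction Networks and Allosteric Hotspot
    Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of protein conformational ensembles for allosteric
    communication. Provides dynamic cross-correlation and generalized
    (mutual-information) correlation matrices, ensemble contact occupancy,
    ensemble-averaged in-silico mutational scanning of binding free energy
    changes with a pluggable substitution scorer, construction of dynamically
    weighted residue interaction networks, shortest-path betweenness
    centrality, and mutational network-perturbation Z-score profiling.
    Includes an elastic-network-model synthetic data generator with analytic
    ground truth so every pipeline stage is testable without external
    trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    bio3d,
    jsonlite,
    yaml,
    rlang,
    Biostrings,
    ggplot2,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    withr
Config/testthat/edition: 3
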