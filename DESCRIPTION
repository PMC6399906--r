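Package: ctsim
Title: Cell-Type Semantic Similarity and Regulatory-Network-Based Cell-Type Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies similarity between cell types by information-content
    (Lin) semantic similarity over an ontology directed acyclic graph parsed
    from OBO flat files, clusters and ranks cell types by their similarity
    profiles, derives cell-specific and shared transcription-factor-to-gene
    regulatory networks from a confidence-scored edge-list compendium, and
    predicts the cell type behind a query gene list with two overlap ratios
    against cell-specific gene universes. Includes deterministic synthetic
    generators for ontologies, network compendia and planted queries so the
    whole pipeline is testable offline, plus a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    graphics,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
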