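Package: ontodriver
Title: Ontology-Based Prediction of Cancer Driver Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts cancer driver genes from ontology-based gene annotations.
    Ontology axioms, class labels, and gene-class associations are rendered
    into a sentence corpus, skip-gram embeddings are trained on the corpus,
    and per-cancer-type feedforward classifiers are evaluated with stratified
    cross-validation. Predicted candidate drivers are validated with three
    statistics: a somatic mutation-frequency comparison (one-tailed Welch
    t-test), a network-module permutation test against an interaction
    network, and per-tool variant pathogenicity-score enrichment (one-tailed
    Mann-Whitney U). Includes a synthetic-data generator that emulates all
    required inputs with planted driver signal, and a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
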