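Package: scavengeR
Title: Hierarchical Classification of Reactive Oxygen Species Scavenging
    Enzymes from Protein Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-level ensemble classifier for reactive oxygen species
    scavenging enzymes (ROSes). Protein sequences are first gated as
    ROSes versus non-ROSes by hard-voting three heterogeneous component
    classifiers (a convolutional network with self-attention on tokenized
    sequences, a feed-forward network on k-spaced amino-acid-group pair
    compositions, and gradient-boosted trees on k-spaced amino-acid pair
    compositions); gated-positive sequences are then assigned an enzyme
    class by soft-voting the class probabilities of the same three
    architectures. Includes the feature encoders (CKSAAP, CKSAAGP,
    frequency-ranked tokenization), a dataset-construction pipeline
    (greedy identity clustering, similarity-ranked hard-negative mining,
    stratified splitting), a motif-based synthetic benchmark generator,
    evaluation utilities (binary and per-class metrics, three-method
    Venn attribution), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    xgboost,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
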