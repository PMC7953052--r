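Package: lppi
Title: Multi-Level Link Prediction on Attributed Protein-Protein
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts protein-protein interactions on large attributed
    networks with a multi-level graph-embedding pipeline: the interaction
    topology is fused with a cosine-similarity graph built from node
    attributes, spectrally coarsened by merging nodes with high spectral
    affinity, embedded on the coarsest level with random-walk methods
    (DeepWalk or node2vec plus skip-gram with negative sampling), refined
    back to full resolution by Laplacian smoothing, and candidate protein
    pairs are classified with L2-regularized logistic regression under
    5-fold cross-validation. Includes a seeded stochastic-block-model
    generator with block-correlated binary attributes so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
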