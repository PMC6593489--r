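Package: edge2vec
Title: Edge-Semantics-Aware Node Embeddings for Heterogeneous Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns node embeddings on heterogeneous (multi edge-type)
    networks such as biomedical knowledge graphs. An edge-type transition
    matrix is estimated by an expectation-maximization loop over biased
    second-order random walks: walk corpora are generated under the current
    matrix and the matrix is re-estimated as the sigmoid-transformed Pearson
    correlation of per-walk edge-type counts. The trained matrix biases the
    walks that feed a skip-gram negative-sampling embedding trainer.
    Includes evaluation harnesses for node multi-class classification,
    pairwise link (bioactivity) prediction and cosine-similarity search
    ranking, seeded synthetic heterogeneous-graph generators with planted
    ground truth, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    e1071,
    pROC
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
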