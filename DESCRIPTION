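Package: esfpa
Title: Elite-Search Flower Pollination Feature Selection for Essential
    Protein Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects informative protein features with a binary Flower
    Pollination Algorithm augmented by an elite search mechanism. Features
    are scored against a "gold standard" derived from mean absolute
    pairwise Pearson correlation, so mutually redundant features are
    penalised. The package also computes six protein-protein interaction
    network centralities (degree, eigenvector, subgraph, information,
    local average connectivity, neighbourhood centrality) and three
    annotation-based scores (Gene Ontology neighbour similarity,
    subcellular compartment weights, protein-complex membership), builds
    balanced essential/non-essential datasets by undersampling, and
    evaluates a seven-learner probability-averaging voting classifier
    under stratified cross-validation. A synthetic-data generator produces
    scale-free interaction networks with planted essential proteins so the
    whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    e1071,
    ranger,
    rpart,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
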