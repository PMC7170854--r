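Package: hinmda
Title: miRNA-Disease Association Prediction from Heterogeneous Network Embeddings
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts candidate miRNA-disease associations by link prediction on a
    five-type heterogeneous biological network (miRNA, lncRNA, protein, disease,
    drug). Node behavior features are learned with a GraRep-style embedding
    (SVD factorization of shifted log k-step transition probability matrices),
    node attribute features come from 3-mer sequence frequencies (miRNA) and
    MeSH-style DAG semantic similarity (disease), a stacked autoencoder maps both
    attribute classes to a uniform dimension, and fused pair vectors are scored
    with a Random Forest under 5-fold cross-validation. Includes a seeded
    synthetic-study generator with planted block signal so the full pipeline is
    testable without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    Biostrings,
    FNN,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
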