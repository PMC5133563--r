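Package: malsite
Title: Sequence-Based Prediction of Lysine Malonylation Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts lysine malonylation sites from protein primary
    sequence. Extracts fixed-length lysine-centered peptide windows with
    dummy-residue padding, encodes each window into a 687-dimensional
    feature vector (k-gram spectrum counts, position-specific residue
    codes, and physicochemical property profiles), selects informative
    features by minimum-Redundancy-Maximum-Relevance (mRMR) mutual
    information ranking, and classifies with a probability-output RBF
    support vector machine. Includes leave-one-out and repeated k-fold
    cross-validation with ROC/AUC and confusion-matrix metrics,
    position-specific two-sample enrichment analysis of peptide sets, a
    synthetic-data generator with controllable positional signal, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    e1071,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
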