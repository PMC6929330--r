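Package: pssmGRU
Title: Order-Preserving Classification of Protein PSSM Profiles with a
    Convolutional Recurrent Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies proteins (adaptor versus non-adaptor) from
    position-specific scoring matrix (PSSM) profiles while preserving the
    positional ordering of the profile. Implements a 1-D convolutional
    front-end with pooling, a gated recurrent unit (GRU) sequence model and
    a sigmoid output head, trained with Adam and inverse-class-frequency
    weighted binary cross-entropy under stratified k-fold cross-validation.
    Also provides the classical order-destroying 400-dimensional summed-PSSM
    representation with k-NN, random forest, SVM and 2-D CNN comparators,
    evaluation metrics (sensitivity, specificity, accuracy, Matthews
    correlation coefficient, ROC/AUC), readers and writers for PSI-BLAST
    ASCII PSSM profiles, FASTA and dataset manifests, and a synthetic PSSM
    generator whose class signal is either purely positional or purely
    compositional.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    class,
    e1071,
    randomForest
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
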