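Package: motifrep
Title: Representation Learning of Sequence Motifs by Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how convolutional neural network architecture
    shapes the motif representations learned from regulatory DNA. Generates
    multi-label synthetic ChIP-seq-like datasets by embedding transcription
    factor motifs into random sequence, trains a controlled family of small
    CNNs that differ only in max-pooling and filter geometry, converts
    trained convolutional filters into position probability matrices by
    aligning their maximally activating subsequences, and quantifies how
    many filters recover the ground-truth motifs with a Tomtom-style
    comparison. Includes sequence-logo plotting and experiment
    orchestration for localist-versus-distributed representation contrasts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    generics,
    jsonlite,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
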