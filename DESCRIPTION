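Package: gcnprio
Title: Disease-Gene Prioritization with a Graph-Convolutional Encoder and a 1-D
    Convolutional Decoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies genes as disease-related or not by encoding a weighted
    gene-interaction network with stacked graph-convolution layers and decoding
    each gene's embedding with a small one-dimensional convolutional network.
    Provides the symmetric degree-normalized propagation operator, an
    end-to-end trainer (Adam, step learning-rate schedule, dropout, batch
    normalization), stratified 10-fold cross-validation with AUC/AUPR
    reporting, a depth ablation and baseline-comparison harness (GCN-only,
    CNN-only, random forest, k-nearest neighbours), a planted-partition
    synthetic benchmark generator, and readers/writers for edge-list,
    expression-matrix and gene-list files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
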