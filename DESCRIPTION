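Package: cardionet
Title: Dense-Concatenation Encoder-Decoder Segmentation of Chest
    Radiographs with Cardiothoracic-Ratio Screening
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multi-class semantic segmentation of posterior-anterior chest
    radiographs (lungs, heart, clavicles) with CardioNet, a shallow
    encoder-decoder that couples dense skip concatenation, depth-wise
    separable convolutions, max-unpooling with pooling indices, and a
    full-resolution feature-boost branch.  Provides a declarative layer
    schedule with shape propagation and parameter auditing, the staged
    flip/translate augmentation cascade, median-frequency class-balanced
    cross-entropy training on CPU, per-class accuracy/Jaccard/Dice
    evaluation, a synthetic chest-phantom generator with analytic ground
    truth, and automated cardiothoracic-ratio (CTR) measurement for
    cardiomegaly screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    EBImage,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
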