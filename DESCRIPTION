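Package: fibroscore
Title: Fibrosity Scoring of Plant-Based Meat Images with a Residual
    Regression Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates continuous fibrosity scores (1-10) of texturized
    vegetable protein (TVP) cross-section images.  Provides spatial
    preprocessing (background removal, zero-padding, centroid centering),
    lossless dihedral and fine-rotation augmentation, a multi-rater score
    data model, a residual convolutional regression network with slow
    reference implementations of every layer operation for oracle
    testing, transfer-learning style training of the fully connected
    head, a regression evaluation suite (error norms, goodness of fit,
    through-origin and ordinary regression slopes), and a synthetic
    food-matrix/air-cell image generator with a rule-based granularity
    oracle used to probe what image features drive the estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    grDevices,
    jpeg,
    png,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    EBImage,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
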