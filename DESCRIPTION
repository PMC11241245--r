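Package: ecsanet
Title: Channel-Spatial Attention Networks for Breast Histopathology Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-class classification of breast-tumor histopathology images with
    an attention-augmented convolutional network (ECSAnet): an EfficientNetV2-S
    style backbone refined by a convolutional block attention module (CBAM) and an
    enlarged fully connected head. Ships the full surrounding pipeline: Reinhard
    stain color normalization in CIELAB, indexing of magnification/class image
    trees (BreakHis layout), stratified splitting, class-balancing oversampling
    with AugMix and geometric augmentation, an SGD training loop with
    plateau-based learning-rate reduction and early stopping, a per-class /
    macro / weighted evaluation suite with ROC-AUC and Jaccard, Grad-CAM
    explanations, and a deterministic synthetic-fixture generator so everything
    runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    withr,
    EBImage,
    Rcpp,
    generics,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
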