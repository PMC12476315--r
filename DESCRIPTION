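Package: LesionSegUQ
Title: Metadata-Fused U-Net Segmentation of Skin Lesions with Monte
    Carlo Dropout Uncertainty
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Binary segmentation of dermoscopic skin-lesion images with a
    U-Net whose bottleneck is fused with a 29-feature vector of histological
    and dermoscopic lesion attributes. Implements five metadata-fusion
    strategies (none, one-hot plus dense, weighted addition, embedding
    concatenation), Bayesian inference by Monte Carlo Dropout, four
    pixel-wise uncertainty estimators (confidence, predictive entropy,
    mutual information, expected pairwise Kullback-Leibler divergence) and
    a weighted aggregate uncertainty score per image. Includes a seeded
    generator of dermoscopy-like images, masks and coupled metadata so the
    whole pipeline is testable without external datasets, plus training
    (BCE and soft-IoU losses, paired augmentation, early stopping),
    evaluation (IoU/Dice), per-attribute performance breakdowns and
    model-comparison reports. The convolutional network engine (forward and
    backward passes, Adam) is implemented in C++ via Rcpp.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    yaml,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
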