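Package: busecho
Title: Breast Ultrasound Phantoms, Feature Extraction, Classification and
    Tumor Segmentation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Toolkit for three-class diagnosis of breast ultrasound images
    (normal, benign, malignant) and pixel-level tumor localization. Provides
    a seeded synthetic speckle-phantom generator with ground-truth masks,
    two feature extractors (a four-Gaussian decomposition of the intensity
    histogram and an eigenface-style covariance projection computed via the
    small-matrix trick), four classical classifiers, two small convolutional
    neural networks (a 16-layer image classifier and an 11-layer pixel
    labeller, trained with seeded Adam), morphological lesion localization,
    and a full evaluation layer (confusion-matrix metrics, ROC/AUC,
    per-image segmentation AUC).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    EBImage,
    minpack.lm,
    e1071,
    rpart,
    caret,
    withr,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
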