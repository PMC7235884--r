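Package: akdl
Title: Shallow Convolutional Network and Classical Baselines for
    Actinic Keratosis Dermoscopy Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for recognizing actinic keratosis (AK) against benign
    keratosis (BK) in dermoscopy images with a shallow LeNet-style
    convolutional network (AK-DL: two 5x5 convolutions with 6 and 16
    filters, one 2x2 max pooling layer, a dropout-regularized fully
    connected head, LeakyReLU activations, momentum SGD training), plus a
    classical baseline built on histogram-of-oriented-gradients
    descriptors with support vector machine, random forest and k-nearest
    neighbour classifiers.  Includes the full preprocessing chain
    (minority-class flip/rotation augmentation, histogram equalization,
    sRGB to CIELAB conversion, bilinear standardization to 64x64x3), a
    seeded two-class synthetic dermoscopy image generator with a tunable
    class-separation parameter, stratified k-fold cross-validation, and
    confusion-matrix metrics (accuracy, sensitivity, specificity,
    precision, Matthews correlation coefficient) with trapezoidal
    ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    e1071,
    randomForest,
    jsonlite,
    grDevices,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
NeedsCompilation: yes
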