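Package: kneekl
Title: Transparent Kellgren-Lawrence Grading of Knee Radiographs with a
    Siamese Convolutional Ensemble
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computer-aided Kellgren-Lawrence (KL) grading of knee
    radiographs built around anatomical symmetry. Localised knee-joint
    regions are intensity-normalised and cropped to a fixed physical size,
    two symmetric lateral/medial patches are extracted (the medial one
    horizontally flipped), and a shared-weight Siamese convolutional
    network maps the pair to a probability distribution over the five KL
    grades. Multiple networks trained from different random seeds are
    fused by summing their pre-softmax outputs, and class-discriminating
    attention maps (a Grad-CAM variant for branch ensembles) are projected
    back onto the joint image. Includes the full training recipe
    (oversampling, on-the-fly augmentation, Adam), an ordinal evaluation
    panel (quadratic weighted kappa, balanced accuracy, grade MSE,
    radiographic-OA ROC/AUC) and a synthetic phantom-radiograph generator
    so the entire pipeline runs at desk scale. The network engine
    (convolution, batch normalisation, pooling, backpropagation, Adam) is
    implemented in the package itself, with compiled kernels for the
    convolution and normalisation hot loops.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
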