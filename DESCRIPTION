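Package: sonotex
Title: Texture-Based Computer-Aided Classification of Thyroid Nodules in
    Ultrasound Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computer-aided diagnosis pipeline for differentiating benign
    from malignant thyroid nodules on B-mode ultrasound texture. Provides a
    hybrid Wiener-Gabor preprocessing filter, gray-level co-occurrence matrix
    (GLCM) texture features with a four-orientation offset sweep, orthonormal
    wavelet subband energy features, a from-scratch AdaBoost ensemble of
    decision stumps with the weighted-majority decision rule, and evaluation
    statistics (sensitivity, specificity, accuracy, ROC/AUC, and logistic
    multiple regression for risk-factor analysis). A synthetic speckle-texture
    image generator emulates the two-class ultrasound setting so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
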