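Package: olpfeat
Title: Interpretable Image-Based Features for Immunosuppressive Therapy
    Response Prediction in Oral Mucosa Pathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An unsupervised workflow that discovers interpretable
    image-based features from unannotated oral-mucosa pathology slides and
    uses them to predict the response to immunosuppressive therapy in oral
    lichen planus. Whole-slide rasters are tiled gaplessly into 128x128
    patches, filtered by four quality-control criteria, compressed into
    2048-dimensional latent vectors by a convolutional autoencoder, and
    clustered with K-means into "features". Each cluster receives an impact
    score I = r+/(r+ + r-) from the label-conditional occupancy of its
    member patches and a weight W = 1 + |0.5 - I|; clusters with W above a
    threshold that are not shape artifacts are key features. Weighted
    per-slide cluster-occupancy vectors feed logistic-regression and
    support-vector classifiers evaluated by stratified 10-fold
    cross-validation with ROC/AUC. Includes a synthetic pseudo-slide
    generator with known texture-class composition so every stage is
    testable end-to-end, the 11-site clinical sign score that defines the
    response label, and polarity-overlay visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    pROC,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    mclust
Config/testthat/edition: 3
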