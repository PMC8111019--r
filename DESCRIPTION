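Package: cxrsearch
Title: Image Search as a Classifier for Pneumothorax Screening in Chest Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Content-based image retrieval treated as a classifier for
    pneumothorax screening on frontal chest radiographs. Images are
    represented by deep-feature descriptors extracted from three
    symmetry-aware views (whole image, left half, horizontally flipped
    right half) under a pluggable frozen backbone; concatenated
    descriptors are optionally compressed to a 256-value code by a
    two-step autoencoder (unsupervised mean-squared-error pre-training
    followed by class-weighted supervised fine-tuning with a sigmoid
    head). A query is classified by the fraction of positive labels
    among its k nearest archived neighbours under Euclidean distance,
    with receiver-operating-characteristic analysis, Youden-index
    operating points, stratified tenfold cross-validation, a principal
    component analysis baseline, and exact Wilcoxon signed-rank fold
    comparisons. Synthetic thorax phantoms and labelled Gaussian
    feature clusters make the whole pipeline testable without any
    external image corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
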