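Package: deepcyto
Title: Segmentation and Classification of Single-Cell Cytology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-cell segmentation and cell-type classification for
    single-cell stained-cytology (Pap smear style) images. Implements a
    U-Net segmenter with optional dilated encoder convolutions and group
    normalization, a residual DCGAN image augmentor with Frechet distance
    evaluation, region-of-interest extraction, single-backbone, majority
    voting and feature-concatenation classifiers, pixel- and label-level
    metric suites, and six end-to-end pipelines combining these stages.
    Ships a synthetic phantom generator so every stage is testable at desk
    scale without external data. All neural-network primitives (convolution,
    pooling, normalization, Adam) are implemented in the package itself via
    'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
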