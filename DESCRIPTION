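Package: cervigrade
Title: Weakly-Supervised Grading of Cervical Dysplasia on Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Sofia", "Almeida", email = "sofia.almeida@example.org",
           role = c("aut", "cre"))
Description: An automated pipeline for grading cervical squamous
    intraepithelial lesions on haematoxylin-eosin whole-slide images.
    The pipeline detects tissue fragments by Otsu thresholding, segments
    the squamous epithelium with a U-Net trained under a combined binary
    cross-entropy and Dice loss, samples 512x512 tiles along the
    morphological centerline of each epithelium ribbon, and grades the
    slide (non-neoplastic, LSIL, HSIL, or non-representative) with an
    ordinal multiple-instance classifier trained under a quadratic
    weighted kappa loss, the slide diagnosis being carried by the worst
    tile. A deterministic phantom-slide generator provides ground-truth
    images, masks and annotations so that every stage is trainable and
    testable on synthetic data, and the metrics module implements the
    evaluation conventions (balanced accuracy, weighted
    precision/sensitivity/F1, quadratic weighted kappa, class exclusion)
    used to score such pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    optparse,
    png,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
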