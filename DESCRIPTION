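Package: feesxai
Title: Explainable Aspiration Detection in Endoscopic Swallowing Videos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An explainable-AI pipeline for detecting aspiration in flexible
    endoscopic evaluation of swallowing (FEES) videos. Provides a synthetic
    endoscopy-scene generator with exact ground truth, frame preprocessing and
    stratified patch sampling, a multi-label 2D U-Net segmentation network for
    glottis region of interest, vocal cords and aspirated bolus (trained with
    Adam, soft Dice loss and Jaccard-based early stopping), connected-component
    post-processing constrained to the glottis ROI, frame-level detection
    metrics (Dice, Jaccard, precision/recall/F1, false-positive frame rates,
    size-versus-Dice rank correlation), and a pixel-count timeline layer that
    surfaces runs of consecutive aspiration frames ("meaningful frames") with
    contour-overlay rendering for human verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    patchwork,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
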