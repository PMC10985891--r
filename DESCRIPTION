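Package: vessel3
Title: Two-Stage Vessel Segmentation for Fetal Three-Vessel-View Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localizing and segmenting the three fetal-heart vessels
    (pulmonary artery, aorta, superior vena cava) in three-vessel-view (3VV)
    ultrasound images. Implements a two-stage pipeline: region-of-interest
    localization by per-class detection-box selection and merging, followed by
    fine multi-class segmentation with a Deeplabv3-style convolutional network
    whose multi-scale head uses dilated branches with hierarchical connections
    and per-branch spatial attention (AMFF), trained with an equally weighted
    class-weighted cross-entropy plus Dice compound loss. Includes a synthetic
    speckle-phantom generator emulating 3VV images, Dice/IoU/Hausdorff
    evaluation metrics, an ASPP-head baseline for ablation, and a compact CPU
    training engine (convolution, batch normalization, spatial attention and
    bilinear resampling with reverse-mode gradients) written in R and
    RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    EBImage,
    pracma
Config/testthat/edition: 3
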