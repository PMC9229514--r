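Package: unet3d
Title: 3D U-Net Semantic Segmentation of Multimodal Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary semantic segmentation of brain-tumor MRI volumes with a
    three-encoder / four-decoder 3D U-Net trained under a class-weighted
    generalized Dice loss. Provides the network builder with a per-layer
    analysis table (activation shapes and learnable-parameter counts), a
    random-patch training datastore with reflection and rotation
    augmentation, an Adam trainer with a piecewise learning-rate schedule,
    whole-volume tiled inference, Dice/sensitivity/specificity evaluation,
    a 4-modality synthetic phantom generator so the full pipeline runs
    without any external download, and minimal NIfTI-1 input/output. The
    computational core (volumetric convolutions and their gradients) is
    implemented in C++ via Rcpp and BLAS.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
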