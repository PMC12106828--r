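Package: histodens
Title: Nuclei-Density-Stratified Classification of H&E Breast Histopathology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end, fully offline pipeline for breast-cancer
    histopathology image analysis: deterministic extraction of overlapping
    224x224 patches from 700x460 fields, Gaussian denoising and optical-density
    H&E colour deconvolution, nuclei segmentation with an attention-gated
    U-Net trained by a built-in CPU backpropagation engine, microscope
    calibration from sensor pixel pitch and magnification to microns per
    pixel, per-patch nuclei density in counts per square millimetre,
    ratio-based stratification into low/medium/high density bins, and
    density-stratified benign-versus-malignant classification with compact
    and depthwise-separable convolutional networks. A seeded synthetic
    H&E scene generator with ground-truth instance masks makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
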