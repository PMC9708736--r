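Package: celmfuse
Title: Multimodal Medical Image Fusion with a Convolutional Extreme
    Learning Machine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixel-selection fusion of co-registered multimodal medical
    images (CT/MRI-like grayscale or SPECT-like pseudo-color pairs). A
    siamese convolutional feature extractor with random kernels feeds an
    extreme learning machine classifier whose output weights are solved in
    closed form by regularized least squares; the resulting per-pixel
    decision map is refined by a 3x3 consistency filter, a windowed-RMSE
    comparison against both sources, and binary morphological smoothing.
    Includes a synthetic training-data and phantom generator, a YUV path
    for color inputs, and four fusion quality metrics (spatial frequency,
    Piella's weighted quality index, normalized mutual information and the
    Chen-Varshney perceptual measure).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
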