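Package: retinet
Title: Multi-Task Convolutional Networks for Retinal Vessel Segmentation
    and Diabetic Retinopathy Grading
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds, profiles and trains compact encoder-decoder
    convolutional networks for retinal fundus images: a cross-stage-partial
    U-shaped vessel segmentation network with atrous spatial pyramid
    pooling, and a hard-parameter-sharing multi-task variant that couples
    per-pixel vessel segmentation with five-grade diabetic retinopathy
    classification.  Includes a from-first-principles parameter and MAC
    accountant, binary cross-entropy plus soft Dice losses, pixel-pooled
    segmentation metrics, a staged multi-task training protocol with
    cosine-annealed Adam, and a deterministic synthetic fundus generator
    with exact vessel masks and grade-conditioned lesions so the full
    pipeline runs on one CPU without external datasets.  All network
    arithmetic (convolution, batch normalisation, bilinear upsampling,
    backpropagation) is implemented in R with small C++ kernels; no deep
    learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    png,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
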