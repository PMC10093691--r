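Package: octacnv
Title: Segmentation and Activity Grading of Choroidal Neovascularization
    in OCTA En-Face Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage analysis of optical coherence tomography angiography
    (OCTA) en-face image pairs for choroidal neovascularization (CNV):
    a parameter-reduced U-Net trained with soft Dice loss segments the CNV
    lesion on the outer-retina slab; classical morphology extracts the
    peripheral-arcade region (vessel binarization, in-mask inversion, ring
    masking) and the perilesional dark halo (contrast-limited equalization
    plus seeded region growing) on the choriocapillaris slab; five binary
    classifiers (frozen-backbone VGG16 transfer heads and a small network
    trained from scratch) grade the five CNV activity criteria, and a lesion
    is called active when at least three criteria are present. Includes a
    synthetic phantom generator with exact ground truth, subject-wise nested
    cross-validation, overlap and confusion-matrix metrics, and a
    command-line pipeline driver. The compact CNN engine (convolution,
    pooling, upsampling, Adam, backpropagation) is implemented in
    RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    EBImage,
    png,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
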