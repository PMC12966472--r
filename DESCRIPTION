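Package: coneUNet
Title: Cone Photoreceptor Detection in Confocal AOSLO Images Using
    Synthetic Training Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for confocal adaptive optics
    scanning laser ophthalmoscope (AOSLO) images of the cone photoreceptor
    mosaic. Generates synthetic cone mosaics with exact ground truth across
    retinal eccentricities, renders them through a Fourier-optics model
    (diffraction and residual Zernike aberrations) with calibrated signal
    and frame-averaged Gaussian noise, builds Gaussian heatmap training
    labels, trains a multi-scale encoder-decoder convolutional network to
    regress cone probability maps, extracts cone centres by thresholded
    peak detection with probability-weighted centroids, and evaluates
    detections against ground truth with one-to-one distance-constrained
    matching and Dice/TPR/FDR summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    Rcpp,
    yaml,
    tiff,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
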