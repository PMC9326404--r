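Package: leafspec
Title: Leaf Potassium Estimation from Hyperspectral Imaging with Wavelet
    Spectra and Image Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric pipeline for estimating leaf potassium content (LKC, %)
    from visible/near-infrared hyperspectral leaf images. Provides a seeded
    synthetic leaf-scene generator with known ground truth, reflectance
    calibration against a gray reference panel, single-band threshold
    segmentation, continuous wavelet transform (sym2) of leaf spectra at dyadic
    scales, characteristic-wavelength selection by competitive adaptive
    reweighted sampling (CARS) and random frog, gray-level co-occurrence matrix
    texture and color-moment image features, and partial least squares
    regression with cross-validated latent-variable choice, together with a
    comparison harness over decomposition scales, selectors and
    spectra-plus-image feature fusions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    png,
    tiff
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
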