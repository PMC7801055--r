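Package: fundusseg
Title: Feature-Fusion U-Net Segmentation of Diabetic Retinopathy Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixel-wise segmentation of diabetic retinopathy lesions
    (microaneurysms, hard and soft exudates, hemorrhages) in color fundus
    photographs. Implements an encoder-decoder convolutional network with
    multiscale feature-fusion (MSFF) encoder blocks, contextual channel
    attention (CCA) decoder fusion, randomized leaky rectifier activations
    and a Balanced Focal Loss for extreme pixel-class imbalance, together
    with the full tile-based pipeline: region-of-interest cropping via Otsu
    thresholding and largest connected component, Gaussian denoising, CLAHE
    contrast enhancement, dataset normalization, sliding-window dicing with
    background-tile elimination, and overlap-averaged reconstruction of
    full-resolution probability maps. A deterministic synthetic fundus
    generator provides paired images and lesion masks so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
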