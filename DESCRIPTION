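Package: lesiontex
Title: Texture-Based Skin Lesion Segmentation, Decomposition and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for classifying dermoscopic skin lesion images from
    texture. Images are decomposed with a multi-resolution empirical mode
    decomposition (MREMD) that forms upper and lower envelopes with fixed-size
    order-statistic windows and dyadic resampling, lesions are localized with a
    Chan-Vese active contour, and max-rotation local binary pattern (LBP)
    histograms are extracted from the lesion area of the image and of its first
    bidimensional intrinsic mode function. The resulting 512 features feed a
    small feed-forward neural network trained by backpropagation with momentum
    and early stopping. Includes one-vs-rest multiclass evaluation metrics and
    a seeded generator of synthetic lesion images with ground-truth masks for
    end-to-end testing without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    generics,
    ggplot2,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
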