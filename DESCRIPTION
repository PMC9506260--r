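Package: rcmseg
Title: Patch-Classifier Heatmap Segmentation of Basal Cell Carcinoma in
    Reflectance Confocal Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects basal cell carcinoma (BCC) regions in in vivo
    reflectance confocal microscopy (RCM) slices by training a small
    depthwise-separable convolutional patch classifier on 256x256 crops
    labelled by a strict-majority rule, convolutionalizing the trained
    classifier into a fully convolutional dense predictor that emits
    per-pixel class-probability heatmaps for whole slices, postprocessing
    heatmaps into binary segmentation masks (Gaussian smoothing,
    thresholding, morphological opening), and evaluating results with
    pixel-level confusion-matrix metrics plus stack- and case-level
    detection criteria under grouped (patient-wise) k-fold
    cross-validation. Includes a synthetic RCM image generator producing
    speckle-textured slices with bright tumor islands ringed by dark
    fissures and pixel-aligned ground-truth masks, organised into stacks
    and cases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
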