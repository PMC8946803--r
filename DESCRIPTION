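Package: hsiclass
Title: Near-Infrared Hyperspectral Classification of Ovarian Tumor Tissue
Version: 0.1.0
Authors@R:
    person("J.", "Kessler", email = "jkessler@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis pipeline for ex vivo tumor detection with a
    snapshot-mosaic near-infrared hyperspectral camera: 5x5 mosaic demosaicing,
    white/dark reference reflectance calibration, per-spectrum min-max
    normalization, glare/background/edge masking, 20x20 patch averaging,
    histology annotation registration (HSV thresholding plus thin-plate-spline
    control-point warps), extraction of 19 prognostic spectral features
    (intensities, derivatives and band ratios), a class-weighted linear
    support vector machine, and leave-one-patient-out cross-validation with
    Youden-index thresholding, AUC and Matthews correlation. Includes a
    synthetic cohort generator that emulates the camera and histopathology
    ground truth so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
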