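Package: frfseg
Title: Fast-Random-Forest Pixel Classification for Histopathology Defect Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trainable pixel classification of photomicrographs in the style of
    fast-random-forest (FRF) segmentation tools: a multiscale filter bank
    (Gaussian, Hessian eigen-features, rotating membrane projections, and
    further texture filters) turns a grayscale image into per-pixel feature
    vectors; a random forest trained on sparse same-image annotations produces
    per-class probability maps; threshold filtering and physical calibration
    quantify the coverage (percent) and extension (mm2) of user-defined defect
    classes.  Includes a calibrated synthetic photomicrograph generator with
    ground-truth masks, performance indicators (precision, recall, ROC), and a
    command-line protocol runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    ranger,
    pROC,
    optparse
Config/testthat/edition: 3
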