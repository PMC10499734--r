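Package: ihccal
Title: Scanner and Staining Calibration for HER2 Immunohistochemistry
    Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage calibration of brightfield immunohistochemistry
    whole-slide-image patches and downstream automated HER2 assessment.
    Stage one removes scanner-dependent colour variation using a colour
    chart slide: incident-light normalization, gamma linearization
    estimated from grayscale-patch luminance, and a white-point-preserving
    polynomial colour correction fitted by equality-constrained least
    squares. Stage two removes staining-batch intensity variation using a
    DAB microbead calibrator slide: bead optical densities define a
    monotone intensity transfer map applied either to the classification
    thresholds (method 1) or to the image itself (method 2). Cells are
    classified into immunoscores from mean membrane DAB optical density,
    giving score percentages, the H-score and an ASCO/CAP-style HER2
    status. Forward models render synthetic chart, calibrator and tissue
    phantom images with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    tiff,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
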