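Package: woundmetry
Title: Calibrated Wound Photography: Chart-Based Color and Scale
    Calibration, Tissue Segmentation and Longitudinal Measurement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative assessment of wound photographs taken
    with ordinary smartphone cameras. A combined fiducial-marker and
    24-patch color chart placed next to the wound is detected
    automatically; a Moore-Penrose pseudo-inverse color transform maps
    observed patch colors onto their reference values and the known
    marker geometry yields a millimetre-per-pixel scale. A two-branch
    encoder-decoder network segments the wound area and its tissue
    composition (epithelial, granulation, necrotic), evaluated with
    intersection-over-union and pixel accuracy under subject-grouped
    nested cross-validation, and segmentations are converted to physical
    areas for longitudinal tracking. A synthetic wound-scene generator
    with exact ground truth makes the full pipeline testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    grDevices,
    jsonlite,
    png,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
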