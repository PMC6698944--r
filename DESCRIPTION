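Package: mrsct
Title: Synthetic CT Generation from T1-Weighted MR by Tissue Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates a synthetic CT (sCT) volume in Hounsfield units from a
    single contrast-enhanced T1-weighted MR head volume for MR-only
    radiotherapy treatment planning. Air cavities are delineated by sparse
    manual contours interpolated across slices; brain, cerebrospinal fluid,
    eyes, cortical and trabecular bone, muscle, fat and contrast artifacts are
    then segmented automatically using patient-specific intensity statistics,
    Canny edge detection with gap closing, and 3D region growing. Each
    tissue's MR intensities are mapped into a calibrated CT-number range
    (bulk, linear or inverse-linear transforms). Includes a digital head
    phantom generator with paired ground-truth CT and label volumes, and
    geometric/electron-density evaluation metrics (external bone contour
    distance, Dice similarity, mean and mean absolute HU error).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
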