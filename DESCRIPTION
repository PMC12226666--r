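Package: ribcwis
Title: Rib Fracture Detection Fusion, CWIS Classification Evaluation, and
    Interobserver Agreement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for automated rib fracture detection and
    Chest Wall Injury Society (CWIS) classification pipelines. Fuses the 3D
    bounding-box outputs of three category-specific detectors (fracture type,
    displacement, location) into single CWIS-labeled detections via greedy
    non-maximum suppression and cross-model consensus, assigns rib numbers
    from numbered rib segmentation volumes, and evaluates detections against
    sphere-encoded reference fractures: sensitivity, precision, F1, false
    positives per scan, per-class tables, confusion matrices, rib-number
    accuracy and operating-point selection. Includes interobserver agreement
    statistics (Cohen's kappa, Krippendorff's alpha, bootstrap confidence
    intervals) and a synthetic rib-cage phantom plus detector simulator so
    the whole pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    caret,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
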