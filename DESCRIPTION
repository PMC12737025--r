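Package: orchidgrader
Title: Multi-View RGB-D Quality Grading of Phalaenopsis Potted Seedlings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for automated A/B/C quality grading of 2.5-inch
    Phalaenopsis potted seedlings from one top-view RGB-D image and eight
    side-view images taken at 45-degree increments. Implements the
    interpretable three-stage pipeline (per-image defect/root detection,
    multi-view consolidation into fixed-length feature vectors, SVR defect
    count estimation, random-forest root grading, and a linear SVM quality
    classifier) as well as a fast direct majority-voting grader; a
    rule-based root grading standard; a weighted defect score with
    calibrated A/B/C score thresholds; RGB-D preprocessing (depth
    alignment, plant masking, extreme-value removal, four-channel fusion,
    fixed side-view cropping, brightness perturbation); YOLO-style
    annotation I/O with a pluggable detector interface; classification and
    regression metrics with confusion-matrix tooling; view-angle ablation
    presets and a brightness robustness sweep; and a fully ground-truthed
    synthetic seedling generator so every stage is testable without the
    original imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    randomForest,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
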