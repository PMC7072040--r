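Package: dxascol
Title: Automated Identification of Scoliosis from Total-Body DXA Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A classical, fully testable implementation of an automated
    DXA Scoliosis Method: synthetic whole-body DXA phantom generation with
    known spinal-curvature ground truth, heuristic anatomical segmentation
    (head, spine, pelvis, two legs), mid-spine likelihood maps and midline
    extraction, tangent-range curvature measurement with three-class grading
    and a logistic suspiciousness score, positioning-error scoring for scan
    exclusion, and a complete diagnostic-validation toolkit (confusion
    tables, sensitivity/specificity, ROC/AUC with bootstrap confidence
    intervals, cut-off sweeps, hypothetical-population projection of
    predictive values, Cohen's kappa repeat-scan reliability, chi-squared
    and t-test association analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    graphics,
    grDevices,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
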