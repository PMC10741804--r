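Package: AutoContourQA
Title: Geometric and Dosimetric Quality Assurance for AI-Assisted
    Radiotherapy Contouring
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Evaluation pipeline for radiotherapy structure sets produced by
    automated contouring tools. Provides voxel-grid containers for binary
    structure masks and 3D dose grids, contour-to-mask rasterization with the
    even-odd rule, anisotropic margin expansion, geometric agreement metrics
    (Dice similarity coefficient, Hausdorff distance, relative volume
    difference), cumulative dose-volume histograms with D_x%, D_cc and V_dose
    statistics, homogeneity and Paddick-style conformity indices, a
    declarative plan-quality scorecard engine with normalized PQM scoring,
    cohort-level summaries with rank-based hypothesis tests, contouring
    time-savings and interobserver variability reports, and a synthetic
    phantom generator with calibrated contour perturbations for end-to-end
    testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
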