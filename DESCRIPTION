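Package: adaptcheck
Title: Fraction-Day CBCT Plan Checks for Adaptive Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Decides, from a fraction-day cone-beam CT, whether an online
    adaptive replan is warranted. Provides isocenter-prealigned rigid and
    B-spline deformable image registration, structure-guided label-mask
    registration for target propagation, CBCT intensity calibration and
    combined-CT splicing, a deterministic ray-tracing dose recomputation
    engine, DVH and 3D gamma analysis with clinical decision thresholds,
    and a synthetic pelvis phantom generator with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports: Rcpp, jsonlite, RNifti, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
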