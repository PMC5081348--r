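Package: saccdecode
Title: Decoding Saccade Amplitude from Multivoxel fMRI Patterns
Version: 0.1.0
Authors@R:
    person("saccdecode", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A reusable, fully synthetic re-implementation of a block-design
    fMRI decoding pipeline for saccadic eye movements: balanced experimental
    design generation, 60 Hz eye-trace simulation with main-sequence
    kinematics, saccade detection and quality control, double-gamma HRF BOLD
    simulation with known multivoxel ground truth, per-block and
    per-condition general linear models, ROI-wise linear support vector
    machine decoding with leave-one-run-out cross-validation and univariate
    feature selection, and group inference by sign-flip maximum-statistic
    permutation tests with family-wise error control across regions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
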