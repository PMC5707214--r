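Package: fpcitbench
Title: Benchmarking Semi-Quantification and Machine-Learning Classifiers for
    FP-CIT SPECT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Head-to-head evaluation of semi-quantification rules and support
    vector machine pipelines for binary classification of (I123)FP-CIT striatal
    uptake. Provides a seeded synthetic cohort and phantom generator with
    age-declining, putamen-dominant and asymmetric striatal binding ratios
    (SBRs); eighteen normative cut-off classifiers (age-matched mean minus k SD,
    minimum, regression bands, ROC optimal operating points); thirteen SVM
    pipelines over SBR, voxel and principal-component features; and a repeated,
    nested, stratified k-fold cross-validation harness with paired fold
    assignments, confusion-matrix metrics and report writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    pracma,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
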