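Package: fallsense
Title: Accelerometer-Based Fall Detection with a Soft-Margin RBF SVM
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects falls in tri-axial waist-mounted accelerometer recordings
    of activities of daily living (ADLs). Provides the four classic action
    parameters (total sum vector, fast changed vector, vertical acceleration,
    posture angle), a frame-labeling rule based on the per-trial peak of the
    fast changed vector, a soft-margin RBF-kernel support vector machine
    detector with an SMO trainer, a boxplot-threshold baseline classifier,
    event-level evaluation (sensitivity, specificity, false positives per
    hour), and a seeded simulator of 21 scripted ADL classes and continuous
    unscripted sessions that stands in for volunteer recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
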