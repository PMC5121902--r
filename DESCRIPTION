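Package: mqc
Title: Matrix-Level Quality Control for High-Throughput Drug Combination Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quality control for pairwise drug-combination screening in
    checkerboard (N x N) matrix format. Computes seven block-level features
    (negative-control level, single-agent and combination-submatrix relative
    standard deviations, Moran's I spatial-autocorrelation p-value, landscape
    smoothness p-value from a penalized additive surface fit, and a
    monotonicity likelihood), fits a multiclass boosted-tree classifier that
    grades each combination response matrix as Good, Medium or Bad with a
    calibrated confidence score, and combines the result with plate-level
    statistics (Z-factor, robust SSMD and their block-control variants) into
    a screen-level quality verdict. Also included: Bliss-independence and
    highest-single-agent synergy statistics, an error-model simulator for
    synthetic screens, rater-consensus utilities (majority vote, Fleiss'
    kappa), classifier validation with multiclass Matthews correlation, and
    an exact trinomial paired-comparison test with Benjamini-Hochberg
    correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    mgcv,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
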