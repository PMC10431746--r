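Package: somameg
Title: Somatosensory MEG Source Connectivity, Gating, and Tactile Acuity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for somatosensory magnetoencephalography at the
    source level: spherical-conductor forward modeling, linearly constrained
    minimum variance (LCMV) beamforming with median-eigenvalue covariance
    regularization, seed-based amplitude-envelope correlation with
    leakage-correcting orthogonalization in alpha and beta bands, paired-pulse
    somatosensory gating of evoked fields, logistic psychometric thresholding of
    two-point discrimination, and vertex-wise brain-behavior statistics with
    threshold-free cluster enhancement (TFCE) and max-statistic permutation
    family-wise error control. Includes a synthetic multi-subject cohort
    generator that plants recoverable ground truth (envelope correlations,
    gating factors, psychometric thresholds, and a connectivity-behavior
    coupling) so that every stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
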