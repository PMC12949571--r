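Package: wmoff
Title: Population Analyses of Persistent Activity and Off States in Working Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing population spiking activity recorded during
    oculomotor delayed-response (spatial working memory) tasks. Implements
    per-unit selectivity and bias-corrected explained-variance (omega-squared)
    time courses, circular-mean preferred-location estimation, a pooled
    inter-spike-interval permutation test for coordinated population silences,
    leave-one-out lasso-logistic population decoding (cross-temporal and binary
    diametric) with posterior-probability confidence, decoder-confidence based
    on/off state labeling with cluster-mass correction, shuffle-debiased state
    tuning curves, simultaneous versus pseudo-population decoding comparisons,
    beta-mixture modeling of confidence, state power spectra, and reaction-time
    and outcome statistics. Includes a synthetic session generator with ground
    truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
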