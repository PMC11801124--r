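Package: avtrack
Title: Audiovisual Neural Speech Tracking with Boosted Temporal Response Functions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the neural tracking of continuous audiovisual
    speech. Extracts acoustic (gammatone spectrogram, auditory-edge onsets) and
    visual (lip aperture) stimulus features, estimates multivariate temporal
    response functions (TRFs) by greedy L2 boosting with nested cross-validation,
    defines percentile-based functional regions of interest, computes the
    acoustic-controlled unique contribution of lip movements to neural tracking,
    and links tracking metrics to behavior through frequentist permutation tests
    (threshold-free cluster enhancement) and Bayesian multilevel regression with
    Student-t errors. A synthetic-data generator with full ground truth makes
    every stage of the pipeline testable without access to neuroimaging
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    coda,
    e1071,
    jsonlite,
    rjags,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
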