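Package: pcohnet
Title: Fused Phase/Amplitude EEG Connectivity and Graph-Convolutional
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds brain functional-connectivity graphs from multichannel
    EEG by fusing the phase lag index (PLI) with magnitude-squared coherence
    (COH) through a piecewise-exponential mapping (P-COH), binarizes them at
    the small-worldness-maximizing threshold, extracts per-channel time- and
    frequency-domain node features with compact LSTM and CNN encoders, and
    classifies segments with a spectral graph-convolutional network.
    Includes a seeded synthetic-cohort generator with controllable pairwise
    phase-lag and amplitude-envelope coupling, a five-fold cross-validation
    harness with bootstrap confidence intervals, Mann-Whitney U validation
    of the fused connectivity, and exporters for brain-network viewers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
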