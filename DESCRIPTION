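Package: arcomp
Title: Frequency-Space-Time Decomposition of the Posterior EEG Alpha Rhythm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes resting-state multichannel EEG into alpha rhythm
    components (ARCs) with distinct frequency, cortical-source, and temporal
    signatures. Implements short-time Fourier spectral tensors, a three-shell
    spherical head model with a LORETA-style linear inverse, two-stage
    non-negative three-way PARAFAC fitted by alternating least squares with
    core-consistency (CORCONDIA) model selection, noise-component rejection
    and labeling of alpha components, group-level cluster-based permutation
    statistics on the source grid, Tucker congruence replicability metrics,
    and a synthetic EEG generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    igraph
Config/testthat/edition: 3
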