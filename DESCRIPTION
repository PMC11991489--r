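Package: mbconn
Title: Muscle-Brain Connectivity Analysis from EEG and EMG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for corticomuscular connectivity studies
    combining multichannel scalp EEG with surface EMG. Implements zero-phase
    preprocessing (band-pass, notch, resampling, mastoid re-referencing,
    epoching with amplitude-based rejection), EMG fatigue spectral features
    (RMS, mean power frequency, median frequency), phase-locking-value
    functional connectivity between sensorimotor regions of interest with
    sparsity-thresholded small-world and efficiency graph metrics against
    degree-preserving null networks, network-based-statistic permutation
    correction for paired designs, and multivariate-autoregressive partial
    directed coherence between motor-cortex channels and muscle. A synthetic
    study generator with analytic ground truth (von Mises phase coupling,
    stable MVAR processes, spectrally shaped EMG surrogates) provides a fully
    reproducible test bed. Recordings are exchanged as EDF or CSV with JSON
    sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
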