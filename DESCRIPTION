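Package: mmnpipe
Title: Oddball ERP Simulation and Cluster-Based Permutation Analysis of the
    Mismatch Negativity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing passive auditory oddball experiments,
    synthesizing multi-channel EEG recordings with injected event-related
    potential (ERP) components, and analysing them the way tone
    mismatch-negativity (MMN) studies do: constrained randomized
    standard/deviant sequences, schematic lexical-tone pitch contours with
    divergence-point detection, 1-20 Hz zero-phase filtering, epoching,
    baseline correction, mean-mastoid re-referencing, multi-rule artifact
    rejection, true and dummy difference waves, MMN/P3a peak and
    mean-amplitude measures, and a from-scratch spatio-temporal
    cluster-based permutation test with sign-flip resampling.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
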