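Package: emgsynergy
Title: Muscle Synergy Extraction and Comparison of Factorisation Methods for EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction of muscle synergies from multi-channel surface
    electromyography (EMG) and systematic comparison of four factorisation
    methods: non-negative matrix factorisation (multiplicative updates),
    principal component analysis, independent component analysis (kurtosis
    contrast with pre-whitening), and factor analysis (principal-axis).
    Includes EMG preprocessing to gait-cycle-normalised activation matrices
    (zero-lag Butterworth band-pass, full-wave rectification, linear
    envelope, amplitude and time normalisation), variance-accounted-for
    model selection, probability-distribution comparison of activation
    patterns and excitation primitives (empirical CDFs, two-sample
    Kolmogorov-Smirnov maximum dissimilarity, occurrence of agreement),
    repeated-measures group statistics, and a seeded generator of
    gait-like synthetic EMG with controllable amplitude-distribution
    kurtosis for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
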