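Package: sospindle
Title: Individualized Slow-Oscillation-Spindle Coupling Analysis for Sleep EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the temporal coordination of slow
    oscillations (<2 Hz) and sleep spindles (10-17 Hz) in multichannel
    sleep EEG. Implements sliding-window spectra with irregular-resampling
    auto-spectral analysis (IRASA) to separate fractal (1/f) from
    oscillatory activity, individualized spindle and slow-oscillation
    event detection, event-locked cross-frequency coupling based on
    circular statistics (coupling strength as mean resultant length,
    preferred phase), slow-oscillation-locked time-frequency maps with
    bootstrap baseline z-scoring, learning-curve parameterization of
    blocked motor-performance scores, and cluster-based permutation
    statistics over sparse electrode montages. A synthetic-data module
    generates ground-truth recordings, hypnograms, and behavioral cohorts
    so every stage can be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
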