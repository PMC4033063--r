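Package: synergait
Title: Motor Module Extraction from Locomotion EMG by Non-Negative Matrix Factorization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting motor modules (muscle synergies) from
    multi-channel surface EMG recorded during walking. Implements the full
    analysis chain: linear-envelope preprocessing with zero-lag Butterworth
    filters, step-cycle segmentation from tibial accelerometry, time
    normalization to a 200-point cycle grid, construction of single-cycle,
    averaged and concatenated factorization inputs, non-negative matrix
    factorization with multiplicative updates (free and fixed-factor
    variants), variance-accounted-for (VAF) reconstruction quality,
    dimensionality selection, module matching by normalized scalar product,
    random-factor baselines, and fixed-weightings cross-reconstruction.
    Includes a seeded synthetic gait-EMG generator that composes envelopes
    from a ground-truth set of motor modules with controllable step-to-step
    amplitude, timing and noise variability, so that the whole pipeline can
    be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
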