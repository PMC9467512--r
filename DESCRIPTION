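Package: beatsync
Title: Neural Synchronization to Musical Features via Temporal Response
    Functions and Reliable Components Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for quantifying cortical tracking of music
    from EEG recordings. Extracts four time-varying musical features from
    audio (gammatone and Hilbert amplitude envelopes, the half-wave
    rectified envelope derivative, binary beat onsets, and spectral flux),
    estimates reliable (correlated) components across participants,
    computes stimulus-response correlation and magnitude-squared
    coherence, fits forward temporal response functions by cross-validated
    ridge regression (univariate, multivariate and residualized variants),
    normalizes synchronization metrics against circular-shift surrogate
    distributions, estimates mutual information between feature pairs, and
    applies cluster-based permutation statistics across tempo conditions.
    Includes a seeded synthetic-data module that generates percussive
    audio with controlled beat tempo and simulated multichannel EEG from
    known convolution kernels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
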