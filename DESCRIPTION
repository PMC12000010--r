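Package: ccca
Title: Channel Component Correlation Analysis for Multi-Channel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts the common feature component shared across the channels
    of a multi-channel EEG recording. Each channel is first decomposed into
    adaptive frequency bands with an empirical wavelet transform (Meyer-type
    filter banks on detected spectral boundaries); a generalized eigenvalue
    problem then finds band weights that maximize the summed cross-channel
    covariance of the weighted band mixtures, subject to a unit total-variance
    constraint. Includes PCA and ICA comparators, evaluation utilities for
    event-related potential (ERP) similarity and steady-state visual evoked
    potential (SSVEP) frequency recognition, a seeded synthetic EEG generator,
    CSV readers/writers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'recording.R'
    'ewt.R'
    'ccca.R'
    'baselines.R'
    'evaluation.R'
    'synthetic.R'
    'io.R'
    'cli.R'
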