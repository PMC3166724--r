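Package: actichain
Title: Sequential Classification of Human Physical Activities from
    Body-Worn Accelerometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Markov-model based sequential classification of human physical
    activities from multichannel accelerometer recordings. Implements sliding
    window segmentation, time and frequency domain feature extraction (DC
    component, spectral energy, spectral entropy of spectrogram coefficients,
    channel correlation coefficients), sequential floating forward-backward
    feature selection with a k-nearest-neighbour criterion, principal component
    rotation, single-frame Gaussian mixture classification, a continuous
    emission hidden Markov model classifier with two-level supervised training
    (count-based initialisation followed by Baum-Welch refinement) and Viterbi
    decoding, likelihood-threshold rejection of spurious frames with ROC-based
    threshold selection, and a generative "virtual experiment" framework that
    simulates activity sequences from an observable Markov chain for validation
    without access to real sensor data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    class,
    jsonlite
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'actichain-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'windowing.R'
    'features.R'
    'selection.R'
    'markov.R'
    'gmm.R'
    'chmm.R'
    'rejection.R'
    'synthetic.R'
    'evaluation.R'
    'serialize.R'
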