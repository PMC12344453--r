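Package: phonosync
Title: Phase Synchrony and Oscillation-Ratio Analysis of Glottal and
    Supraglottic Voice Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing irregular voice production as a system of
    coupled glottal and supraglottic oscillators. Extracts glottal and
    supraglottic area waveforms from grayscale high-speed laryngeal frame
    stacks by threshold segmentation, tracks fundamental frequency with a
    YIN-family estimator, detects subharmonics, frequency jumps and
    biphonation from short-term Fourier spectrograms, computes windowed
    Hilbert-phase synchrony between channel pairs (reported as per-window
    medians and quartiles), estimates integer glottal-to-supraglottic
    oscillation ratios, and classifies phonation regimes. A seedable
    synthetic scene generator produces multi-channel recordings (audio-like,
    inverted-electroglottogram-like and area-waveform channels plus rendered
    frame stacks) with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    tiff,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'accessors.R'
    'utils.R'
    'signal-io.R'
    'synth-scene.R'
    'render.R'
    'segmentation.R'
    'fo.R'
    'spectral.R'
    'phase-synchrony.R'
    'ratio.R'
    'pipeline.R'
    'phonosync-package.R'
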