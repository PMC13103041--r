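Package: ssvepshape
Title: Waveform-Shape Decoding of Visual Scenes from Flicker-Evoked EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding natural visual scenes and participant identity
    from the waveform shape of steady-state visually evoked potentials
    (SSVEPs) recorded with flickering LCD glasses. Implements the full
    analysis chain: reading continuous EEG (BrainVision or delimited text),
    flicker-trigger segmentation, peak-to-peak artifact rejection on EOG and
    accelerometer channels, zero-phase Butterworth band-pass and 50 Hz notch
    filtering, one-period epoch averaging, Pearson-correlation score-based
    decoding (and peak-to-peak amplitude, endogenous alpha power and
    participant-identity variants), data-duration and harmonic band-pass
    sweeps, simulated chance-level null distributions with Bonferroni
    corrected significance thresholds, and paired sign-flip permutation
    tests. A synthetic-EEG generator with per-participant, per-scene harmonic
    waveforms, 1/f background noise, an individual alpha oscillator,
    eye-blink transients and head-motion bursts makes every stage testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
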