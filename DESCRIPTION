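Package: fetalmove
Title: Fetal Movement Detection from Multichannel Vibroacoustic Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting fetal movement from a
    six-channel abdominal vibroacoustic sensor array recorded alongside
    ultrasound scanning. Provides a synthetic-session generator emulating
    ultrasound-annotated recordings (movement bursts of four classes, probe
    motion artefacts co-registered with an IMU channel, maternal push-button
    presses), a signal-cleaning chain (offset removal, RMS normalisation,
    IMU-gated artefact zeroing, push-button synchronisation, 30 Hz Kaiser FIR
    low-pass), short-time Fourier transform featurisation under three sensor
    fusion strategies (per-sensor, concatenated, summed), from-scratch
    classifiers for imbalanced data (k-nearest neighbours, Gini decision
    trees, AdaBoost.M1 and RUSBoost), and evaluation utilities: confusion
    matrix aggregation across sensors and scans, chronological train/test
    splits, IMU-threshold and STFT grid searches, movement-count correlation,
    and agreement between maternally perceived and ultrasound-detected
    movements.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    graphics,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
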