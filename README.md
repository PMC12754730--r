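# fetalmove

Detection of fetal movement from a six-channel abdominal vibroacoustic
sensor array (three piezoelectric, three acoustic contact sensors sampled at
512 Hz), validated against movements called out by a sonographer during
ultrasound scanning. The package is aimed at biomedical-signal researchers
who want a reproducible, tested implementation of the full analysis chain —
from raw multichannel recordings to cross-scan performance tables — and a
synthetic-session generator to exercise it, since the clinical recordings
behind this class of study are not publicly deposited.

## What it implements

**Signal cleaning.** Push-button synchronisation; per-channel offset removal
(mean subtraction) and RMS normalisation; zeroing of sensor samples where
the ultrasound-probe IMU magnitude |a| exceeds a threshold τ ∈ {4, 5, 6}
(default 5); a linear-phase Kaiser-window FIR low-pass (30 Hz passband edge,
40 dB stopband at 35 Hz) with group-delay compensation.

**Features.** Magnitude STFT with 8 s Hann windows and 2 s overlap (6 s
hop), 0.125 Hz resolution, bins kept up to 30 Hz (241 bins). Windows are
labelled movement if any ultrasound-detected event overlaps them. Three
fusion strategies: per-sensor (model input 1), feature-wise concatenation of
the six spectrograms (model input 2, 6 × 241 features), and element-wise
summation (model input 3).

**Classifiers** (all implemented in-package with a common fit/predict
contract): k-nearest neighbours; a weighted decision tree with exhaustive
Gini splits; AdaBoost.M1 on depth-1 stumps with vote weights
αₜ = ½ ln((1 − εₜ)/εₜ); and RUSBoost, which fits each round's stump on a
random-undersampled 50:50 subset while computing εₜ and the weight update on
the full training set — the imbalance-aware model the analysis selects.

**Evaluation.** Precision TP/(TP+FP), recall TP/(TP+FN), harmonic-mean F1,
specificity and accuracy, with movement as the positive class; element-wise
averaging of confusion counts across sensors (strategy 1) and across scans;
chronological 70/30 train/test splits; the IMU-threshold search over
{4, 5, 6} on the busiest scan; the STFT grid search (windows 2–10 s,
overlaps 1–4 s); per-scan performance versus movement count with Spearman
rank correlation; and the agreement analysis between maternally perceived
(push-button) and ultrasound-detected movements.

**Synthetic sessions.** `session_config()` defaults encode the study
conditions: 30-minute sessions, ~240 one-second movement events (13%
active time), four movement classes, 0.61 perception probability, probe
artefacts co-registered with the IMU channel, per-channel gains, offsets
and noise. Generation is bit-reproducible from one integer seed.

## Worked example

```r
library(fetalmove)

dir <- tempfile(); data_dir <- file.path(dir, "scans")

# two 5-minute synthetic scans (all other conditions at study defaults)
fm_simulate(list(duration_s = 300), data_dir, n_scans = 2, seed = 42)

# concatenated-spectrogram fusion + RUSBoost, 70/30 chronological split
fm_run(list(classifier = "rusboost", model_inputs = 2,
            classifier_args = list(n_estimators = 50)),
       data_dir, file.path(dir, "out"), seed = 42)
#>   model_input classifier precision recall        f1 specificity  accuracy
#> 1           2   rusboost 0.8571429    0.6 0.7058824        0.75 0.6428571

# agreement between button presses and ultrasound annotations
fm_agreement(data_dir, file.path(dir, "agree"))
#>   scan_id n_events  accuracy precision    recall specificity
#> 1  scan01       45 0.7105263 0.5111111 0.6206897           1
#> 2  scan02       37 0.7105263 0.5675676 0.5600000           1
```

The run writes `results.csv` (one row per fusion-strategy/classifier cell),
`per_scan.csv` (confusion counts per scan, per sensor for strategy 1) and a
`manifest.json` with the config, seed and file hashes. Precision here is
the fraction of predicted-movement windows that truly contain movement;
recall the fraction of movement windows recovered; the agreement table's
precision is the fraction of ultrasound-detected movements the participant
signalled (≈ the 0.61 perception probability, noisy at 5-minute scale).
Absolute values on synthetic data are not clinical performance claims.

Lower-level functions expose every stage: `generate_recording()`,
`preprocess_recording()`, `compute_stft()`, `fuse_concatenated()`,
`fm_rusboost()`, `run_experiment()`, `imu_threshold_search()`,
`stft_grid_search()`, `mpm_vs_udfm_agreement()`. A thin command-line
wrapper lives at `inst/cli/fmwear.R`. The methods vignette
(`vignettes/fetal-movement-detection.Rmd`) documents the model, parameter
choices and limitations.

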