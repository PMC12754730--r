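---
title: "Detecting fetal movement from a vibroacoustic sensor array"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fetal movement from a vibroacoustic sensor array}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Maternal perception is still the dominant out-of-clinic signal of fetal
wellbeing, but it is subjective and misses many movements; ultrasound is
objective but sporadic, expensive and operator-bound. A low-cost wearable
alternative is an abdominal array of contact vibration sensors — here three
piezoelectric and three acoustic (MMG) transducers — recorded at 512 Hz
alongside a 30-minute ultrasound session in which a sonographer calls out
movements in real time. Those ultrasound-detected fetal movements (UDFM)
are the gold-standard labels; a push button records maternally perceived
movements (MPM); an IMU on the ultrasound probe marks the periods when
probe motion contaminates the sensors.

`fetalmove` implements that analysis end to end: a synthetic-session
generator (the clinical recordings are not publicly deposited), the
signal-cleaning chain, STFT featurisation under three sensor-fusion
strategies, from-scratch classifiers suited to imbalanced labels, and the
evaluation protocol, including the cross-sensor/cross-scan confusion-matrix
averaging and the two hyperparameter searches.

## The synthetic-data generator

`session_config()` fixes the study conditions: 1800 s sessions at 512 Hz,
an expected 240 movement events of ~1 s mean duration (so the expected
movement-active fraction is 240/1800 = 13.3%), four event classes
(`general`, `breathing`, `startle`, `limb`) differing only in duration and
amplitude distributions, a 0.61 probability that an event is maternally
perceived (pressed 0--2 s after onset), per-channel gains, noise levels
and constant offsets, and probe-motion artefact episodes.

Design choices worth knowing:

* **Event waveform.** Events are damped sinusoid packets with a random
  1--25 Hz carrier under a smooth Hann-squared attack, so their energy sits
  below the 30 Hz band edge. The clinical papers in this area do not
  publish per-event morphology; this waveform is a stand-in that satisfies
  the documented spectral constraint, not a claim about the true signals.
  Breathing events additionally carry a slow ~1 Hz amplitude modulation.
* **Per-sensor heterogeneity.** Each event is scaled per channel by a
  modality factor (acoustic sensors attenuated to 0.7 of piezo) and a
  random log-normal emphasis, mimicking the way a movement couples
  differently into each sensor.
* **IMU scale.** The quiescent IMU channel has unit variance, and probe
  episodes raise it to 4--8x that level, so the integer gating thresholds
  4, 5 and 6 are meaningful absolute values. Artefact bursts are added to
  the sensor channels only at samples where the IMU is elevated.
* **Non-overlapping events.** Ultrasound call-outs are discrete single
  events, so onsets are rejection-sampled to avoid overlap.
* **Seeding.** One integer seed expands into independent substreams per
  stochastic component (events, perception, each sensor channel, IMU,
  probe episodes), so channel `k` is reproducible regardless of how many
  channels are generated, and repeated calls are bit-identical.

What the generator deliberately does not model: biomechanics of the
abdomen, gestational-age dependence, maternal heart/respiration artefacts,
or sensor transfer functions. Passing tests on this data shows the
pipeline's statistical machinery works under the documented conditions; it
does not certify clinical performance.

## The cleaning chain

`preprocess_recording()` applies, in a fixed order:

1. **Synchronisation** — the first button press (trial-pressed at session
   start) becomes `t = 0`; earlier samples are dropped and annotations are
   shifted identically.
2. **Offset removal** — subtract each channel's mean.
3. **RMS normalisation** — divide each channel by its root-mean-square, so
   channels of widely varying amplitude become comparable.
4. **IMU-gated artefact zeroing** — every sample where the raw IMU
   magnitude exceeds the threshold (default 5) is set to zero in all sensor
   channels. The threshold applies to the *un-normalised* IMU: its
   candidate values (4, 5, 6) are absolute, and normalising the IMU would
   strip their meaning. Gating is idempotent, and an optional `guard_s`
   dilates the zeroed region (default 0: only coincident samples).
5. **30 Hz low-pass** — fetal movements live below ~30 Hz, so a
   linear-phase Kaiser-window FIR (passband edge 30 Hz, stopband edge
   35 Hz, 40 dB attenuation, 0.5 dB ripple — the loosest design consistent
   with the published response) removes everything above. A single forward
   pass is used with group-delay compensation (the order is forced even and
   the output shifted by half the filter length), keeping labels
   time-aligned.

Two orderings are genuinely open in the source description and were fixed
here: RMS normalisation happens *before* gating (so the sensor scale is
already unit when samples are zeroed, keeping the gate scale-free for the
sensors), and the RMS is computed over the whole channel including samples
that the gate later zeroes (excluding them would couple the normalisation
to the gating threshold).

## Features and fusion

`compute_stft()` uses 8 s Hann-tapered windows with a 2 s overlap between
consecutive windows — i.e. a 6 s hop ("overlap" is read as the shared
duration, which is what makes the published 1--4 s overlap grid sensible) —
giving a 1/8 = 0.125 Hz frequency resolution; bins above 30 Hz are
discarded (241 bins). Magnitude (not power) spectra are used so the summed
fusion stays linear in the per-sensor spectra; this and the Hann taper are
explicit choices where the source is silent.

A window is labelled movement if *any* UDFM event overlaps it by a positive
duration — a majority rule would miss 1 s events inside 8 s windows. All
four classes map to the single positive label. Gated (zeroed) stretches are
retained as ordinary windows rather than excluded; they carry near-zero
spectra and act as negatives unless an event overlaps them.

The three fusion strategies (`fuse_individual()`, `fuse_concatenated()`,
`fuse_summed()`) correspond to per-sensor analysis (six models whose
confusion counts are averaged), feature-wise concatenation in the fixed
array order PZ_a1 ... PZ_a6 (1446 features), and element-wise summation of
the six magnitude spectrograms (241 features).

## Classifiers

All four classifiers are implemented in-package with a shared
`fit`/`predict` contract (the evaluation layer is model-agnostic), and all
ties break toward class 0 — a conservative "no movement" default that also
fixes determinism:

* `fm_knn()` — brute-force k-nearest neighbours (default k = 3, Euclidean;
  Manhattan/Chebyshev/Minkowski and inverse-distance weighting available).
* `fm_tree()` — binary decision tree; every split exhaustively searches all
  features and all boundaries between distinct sorted values, minimising
  weighted Gini impurity (entropy optional). Per-sample weights make it the
  boosting weak learner.
* `fm_adaboost()` — AdaBoost.M1 on depth-1 stumps, 100 rounds by default.
  A perfect round (`eps = 0`) is kept with its error floored at `1/(2n)`;
  a round no better than chance stops boosting.
* `fm_rusboost()` — identical boosting backbone, but each round fits its
  stump on a random-undersampled subset (majority class cut to the
  minority size, 50:50 by default) using the current full-set weights
  restricted to it; the weighted error and weight update always use the
  full training set. Rounds with `eps >= 0.5` are discarded and resampled
  (up to 10 consecutive attempts, after which the ensemble stops early —
  with hard binary labels this truncation is a genuine property of the
  M1-style scheme on heavily overlapping classes).

AdaBoost.M1 rather than M2 is used for both boosted models: with two
classes the M2 pseudo-loss machinery reduces to M1 weighting. The source
work does not report k, tree depth, ensemble size or learning rate; the
defaults above are explicit choices, not recovered settings.

## Evaluation protocol

Movement is the positive class. `metrics()` implements precision
`TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 as their harmonic mean, specificity
and accuracy; zero-denominator metrics are flagged `NA` rather than
silently zeroed. For the per-sensor strategy, the six sensor matrices are
averaged element-wise into a per-scan matrix, per-scan matrices are
averaged across scans, and metrics come from the final averaged counts
(`aggregate_model1()`); the concatenated and summed strategies skip the
sensor level (`aggregate_model23()`). Computing F1 from the averaged
precision/recall reproduces the internal consistency of the published
per-strategy table.

The 70/30 split is chronological within each scan (first 70% of windows
train): windows overlap in time, so a random split would leak test windows
into training. The training size is clamped to leave at least one test
window.

`imu_threshold_search()` follows the published protocol: the single scan
with the most UDFM events is evaluated at thresholds 4, 5 and 6, and the
threshold maximising the mean of precision and recall is selected.
`stft_grid_search()` scans windows 2--10 s by overlaps 1--4 s (30 valid
pairs after dropping `overlap >= window`), maximising F1 with ties toward
the larger window, then the smaller overlap.

`mpm_vs_udfm_agreement()` discretises a session into non-overlapping 8 s
windows and compares UDFM-positive windows (reference) against MPM-press
windows (test) for accuracy, recall and specificity. Its *precision* is
event-level — the fraction of ultrasound-detected movements that were
signalled by a press, estimated as presses/events — because the window-level
ratio is biased by multi-event windows and press/window boundary crossings,
whereas every press corresponds to exactly one perceived event by
construction. On generator output this recovers `perception_prob` to
binomial accuracy.

## Numerical and degenerate-input conventions

* All-zero (or constant) sensor channels fail RMS normalisation with an
  error naming the channel.
* Single-class training windows (a scan whose training portion has no
  events, or only events) fall back to a constant majority predictor with
  a warning, so multi-scan runs complete.
* Empty annotation tracks label every window 0; undefined metrics
  propagate as `NA` and are reported, never imputed.
* Boosting weight updates renormalise to sum 1 each round; the training
  error bound `prod(2 sqrt(eps(1-eps)))` is asserted in the tests.
* Split-selection ties in the tree go to the lowest feature index and
  threshold, keeping fits deterministic.

## Problem sizes used in the shipped tests

The test suite and acceptance script size their simulations for a desk
machine: unit tests use 10--300 s sessions (the generator scales the event
rate with duration, preserving the 13% active fraction); the paired
boosting comparison uses 10 datasets of 2000 samples at 13% positive —
about the scale of one study's pooled training windows; the end-to-end
check simulates three full 1800 s sessions and runs all three fusion
strategies with RUSBoost. The methods themselves carry no scale
assumptions beyond "at least one analysis window".

## Known limitations

* Synthetic recordings only: the clinical numbers of the source study
  (absolute precision/recall on real scans) are not reproducible here and
  are checked only directionally (e.g. undersampled boosting recalling
  more positives than plain boosting at 13% prevalence).
* The 8 s / 2 s STFT default makes neighbouring windows share 2 s of
  signal; the chronological split avoids leakage between train and test,
  but window labels remain correlated in time.
* The agreement analysis assumes one press per perceived movement and no
  spurious presses; real button data would need press de-duplication.
* No probability calibration, no per-class (4-way) movement labelling, no
  SMOTE-style oversampling — all outside the scope of the analysis this
  package reproduces.
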