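# Shared fixtures: small session configs, hand-built annotation tracks and
# independent brute-force oracles used across the tests.

tiny_config <- function(duration_s = 60, seed = 1L, ...) {
  session_config(duration_s = duration_s, seed = seed, ...)
}

# Hand-built annotation track (same structure the generator emits).
make_track <- function(onsets = numeric(0), durations = numeric(0),
                       classes = rep("general", length(onsets)),
                       perceived = rep(TRUE, length(onsets)),
                       mpm = numeric(0), sync = 0, scan_id = "fixture") {
  structure(list(
    events = data.frame(onset_s = onsets, duration_s = durations,
                        class = classes, perceived = perceived,
                        stringsAsFactors = FALSE),
    mpm_s = mpm, sync_press_s = sync, scan_id = scan_id),
    class = "fm_track")
}

# Hand-built recording (same structure the generator emits).
make_recording <- function(sensors, imu = NULL, button = NULL, fs = 64,
                           scan_id = "fixture") {
  n <- nrow(sensors)
  colnames(sensors) <- fm_channels()[seq_len(ncol(sensors))]
  if (is.null(imu)) imu <- numeric(n)
  if (is.null(button)) { button <- numeric(n); button[1] <- 1 }
  structure(list(sensors = sensors, imu = imu, button = button, fs = fs,
                 subject_id = "s", scan_id = scan_id, gestation_weeks = 34),
            class = "fm_recording")
}

# O(n*m) interval-intersection oracle for window labelling.
oracle_labels <- function(starts, window_s, events) {
  vapply(starts, function(s) {
    hit <- FALSE
    for (i in seq_len(nrow(events))) {
      a <- max(s, events$onset_s[i])
      b <- min(s + window_s, events$onset_s[i] + events$duration_s[i])
      if (b - a > 0) hit <- TRUE
    }
    as.integer(hit)
  }, integer(1))
}

# Exhaustive distance-sort kNN oracle (euclidean, uniform votes, tie -> 0).
oracle_knn <- function(train_x, train_y, query, k) {
  apply(query, 1, function(q) {
    d <- sqrt(colSums((t(train_x) - q)^2))
    nn <- order(d)[seq_len(k)]
    v1 <- sum(train_y[nn] == 1)
    as.integer(v1 > k - v1)
  })
}

# Brute-force pairwise confusion tally.
oracle_confusion <- function(yt, yp) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(yt)) {
    if (yt[i] == 1 && yp[i] == 1) tp <- tp + 1
    if (yt[i] == 0 && yp[i] == 0) tn <- tn + 1
    if (yt[i] == 0 && yp[i] == 1) fp <- fp + 1
    if (yt[i] == 1 && yp[i] == 0) fn <- fn + 1
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# FFT amplitude of a sinusoid at a given frequency (steady-state section).
fft_peak_amplitude <- function(x, fs, f) {
  n <- length(x)
  X <- abs(stats::fft(x)) / n * 2
  X[round(f * n / fs) + 1]
}

# Imbalanced overlapping-class feature data: `frac_pos` positives shifted by
# `shift` in the first two of `p` standard-normal features.
make_imbalanced <- function(n = 400, frac_pos = 0.13, p = 4, shift = 1.2,
                            seed = 1) {
  set.seed(seed)
  y <- as.integer(runif(n) < frac_pos)
  X <- matrix(rnorm(n * p), n, p)
  X[y == 1, 1:2] <- X[y == 1, 1:2] + shift
  list(X = X, y = y)
}

# Small synthetic dataset wrapped as an fm_dataset.
make_dataset <- function(X, y, starts = seq_len(nrow(X)) - 1, scan_id = "fx") {
  ds <- fuse_summed(list(structure(list(
    magnitudes = t(X), freqs_hz = seq_len(ncol(X)),
    window_starts_s = starts, channel_id = "fx",
    config = spectral_config()), class = "fm_spectrogram")), y, scan_id)
  ds
}
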