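# STFT featurisation and the three sensor-fusion strategies.

#' Spectral analysis configuration
#'
#' Sliding-window STFT parameters. With the default 8 s window at 512 Hz
#' the frequency resolution is 1/8 = 0.125 Hz; "overlap" is the duration
#' shared by consecutive windows, so the hop is `window_s - overlap_s`
#' (6 s at the defaults).
#'
#' @param window_s Analysis window length in seconds (default 8).
#' @param overlap_s Overlap between consecutive windows in seconds
#'   (default 2); must satisfy `0 < overlap_s < window_s`.
#' @param fs Sampling rate in Hz (default 512).
#' @param max_freq_hz Highest frequency bin retained (default 30 Hz, the
#'   band edge of the low-pass filter).
#' @return An object of class `spectral_config` with derived fields
#'   `hop_s` and `freq_res_hz`.
#' @export
spectral_config <- function(window_s = 8, overlap_s = 2, fs = 512,
                            max_freq_hz = 30) {
  stopifnot_scalar_pos(window_s, "window_s")
  if (overlap_s <= 0 || overlap_s >= window_s)
    stop("'overlap_s' must satisfy 0 < overlap_s < window_s", call. = FALSE)
  structure(list(window_s = window_s, overlap_s = overlap_s, fs = fs,
                 max_freq_hz = max_freq_hz,
                 hop_s = window_s - overlap_s,
                 freq_res_hz = 1 / window_s),
            class = "spectral_config")
}

#' Number of STFT windows for a signal
#'
#' `floor((n_samples - window) / hop) + 1` for windows starting at sample
#' 0, hop, 2 hop, ...
#' @param n_samples Signal length in samples.
#' @param config A [spectral_config()].
#' @return Window count (0 if the signal is shorter than one window).
#' @export
n_stft_windows <- function(n_samples, config) {
  nwin <- round(config$window_s * config$fs)
  hop <- round(config$hop_s * config$fs)
  if (n_samples < nwin) return(0L)
  as.integer((n_samples - nwin) %/% hop + 1L)
}

#' Magnitude STFT of one channel
#'
#' Hann-tapered frames of `window_s` seconds starting every
#' `window_s - overlap_s` seconds; the magnitude spectrum of each frame is
#' kept up to `max_freq_hz` (inclusive), giving
#' `floor(max_freq_hz * window_s) + 1` frequency bins spaced `1/window_s` Hz.
#'
#' @param signal Numeric vector, at least one window long.
#' @param config A [spectral_config()].
#' @param channel_id Label stored on the spectrogram.
#' @return An object of class `fm_spectrogram`: `magnitudes`
#'   `[n_freq_bins x n_windows]`, `freqs_hz`, `window_starts_s`,
#'   `channel_id`, and the config.
#' @export
compute_stft <- function(signal, config = spectral_config(), channel_id = "") {
  stopifnot(inherits(config, "spectral_config"))
  nwin <- round(config$window_s * config$fs)
  hop <- round(config$hop_s * config$fs)
  if (length(signal) < nwin)
    stop("signal shorter than one analysis window", call. = FALSE)
  nw <- n_stft_windows(length(signal), config)
  starts <- (seq_len(nw) - 1L) * hop
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, nwin - 1) / (nwin - 1))
  idx <- outer(seq_len(nwin), starts, `+`)
  frames <- matrix(signal[idx], nwin, nw) * taper
  sp <- stats::mvfft(frames)
  freqs <- (seq_len(nwin) - 1L) * config$fs / nwin
  keep <- freqs <= config$max_freq_hz + 1e-9
  structure(list(magnitudes = Mod(sp[keep, , drop = FALSE]),
                 freqs_hz = freqs[keep],
                 window_starts_s = starts / config$fs,
                 channel_id = channel_id,
                 config = config),
            class = "fm_spectrogram")
}

#' @export
print.fm_spectrogram <- function(x, ...) {
  cat("Spectrogram", x$channel_id, ":", nrow(x$magnitudes), "freq bins (<=",
      x$config$max_freq_hz, "Hz, step", format(x$config$freq_res_hz), "Hz) x",
      ncol(x$magnitudes), "windows\n")
  invisible(x)
}

#' @export
plot.fm_spectrogram <- function(x, ...) {
  graphics::image(x$window_starts_s, x$freqs_hz, t(x$magnitudes),
                  xlab = "time (s)", ylab = "frequency (Hz)",
                  main = paste("STFT", x$channel_id), ...)
  invisible(x)
}

#' Binary movement labels for STFT windows
#'
#' A window is labelled 1 (movement) if any ultrasound-detected event
#' overlaps `[start, start + window_s)` by a positive duration; all four
#' movement classes map to 1 and everything else to 0.
#'
#' @param window_starts_s Sorted window start times in seconds.
#' @param config The [spectral_config()] the windows came from.
#' @param track An `fm_track`.
#' @return Integer 0/1 vector aligned with `window_starts_s`.
#' @export
label_windows <- function(window_starts_s, config, track) {
  ev <- track$events
  y <- integer(length(window_starts_s))
  if (nrow(ev) == 0) return(y)
  ends <- window_starts_s + config$window_s
  for (i in seq_len(nrow(ev))) {
    hit <- ev$onset_s[i] < ends & ev$onset_s[i] + ev$duration_s[i] > window_starts_s
    y[hit] <- 1L
  }
  y
}

# Shared-grid check for the fusion operations.
check_grids <- function(spectrograms) {
  ref <- spectrograms[[1]]
  for (s in spectrograms[-1]) {
    if (!isTRUE(all.equal(s$window_starts_s, ref$window_starts_s)))
      stop("spectrograms do not share a window grid", call. = FALSE)
    if (!isTRUE(all.equal(s$freqs_hz, ref$freqs_hz)))
      stop("spectrograms do not share a frequency-bin grid", call. = FALSE)
  }
  invisible(ref)
}

new_dataset <- function(X, y, starts, scan_id, fusion, sensor_id) {
  stopifnot(nrow(X) == length(y), nrow(X) == length(starts))
  structure(list(X = X, y = as.integer(y), window_starts_s = starts,
                 scan_id = scan_id, fusion = fusion, sensor_id = sensor_id),
            class = "fm_dataset")
}

#' @export
print.fm_dataset <- function(x, ...) {
  cat("Windowed dataset (", x$fusion, ", sensor ", x$sensor_id, "): ",
      nrow(x$X), " windows x ", ncol(x$X), " features, ",
      sum(x$y), " positive\n", sep = "")
  invisible(x)
}

#' Fusion strategy 1: one dataset per sensor
#'
#' Each sensor's spectrogram becomes its own feature matrix
#' (windows x frequency bins); the label vector is shared.
#'
#' @param spectrograms List of six `fm_spectrogram`s on a common grid.
#' @param y Binary labels from [label_windows()].
#' @param scan_id Identifier stored on the datasets.
#' @return List of `fm_dataset`, one per sensor, in array order.
#' @export
fuse_individual <- function(spectrograms, y, scan_id = "") {
  ref <- check_grids(spectrograms)
  lapply(spectrograms, function(s)
    new_dataset(t(s$magnitudes), y, ref$window_starts_s, scan_id,
                "individual", s$channel_id))
}

#' Fusion strategy 2: concatenated spectrograms
#'
#' The six spectrograms are stacked feature-wise: for each window the
#' feature vector is sensor 1's bins, then sensor 2's, ..., in the fixed
#' array order, giving `6 x n_freq_bins` features.
#'
#' @inheritParams fuse_individual
#' @return A single `fm_dataset` with the concatenated features.
#' @export
fuse_concatenated <- function(spectrograms, y, scan_id = "") {
  ref <- check_grids(spectrograms)
  X <- do.call(cbind, lapply(spectrograms, function(s) t(s$magnitudes)))
  colnames(X) <- unlist(lapply(spectrograms, function(s)
    paste0(s$channel_id, "_", format(s$freqs_hz, trim = TRUE))))
  new_dataset(X, y, ref$window_starts_s, scan_id, "concatenated", "all")
}

#' Fusion strategy 3: summed spectrograms
#'
#' The six magnitude spectrograms are summed element-wise into one
#' composite spectrogram of the original dimensions.
#'
#' @inheritParams fuse_individual
#' @return A single `fm_dataset` with `n_freq_bins` features.
#' @export
fuse_summed <- function(spectrograms, y, scan_id = "") {
  ref <- check_grids(spectrograms)
  M <- Reduce(`+`, lapply(spectrograms, function(s) s$magnitudes))
  new_dataset(t(M), y, ref$window_starts_s, scan_id, "summed", "all")
}
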