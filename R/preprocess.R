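# Signal-cleaning chain applied before featurisation, in fixed order:
# push-button synchronisation -> per-channel offset removal -> per-channel
# RMS normalisation -> IMU-gated probe-artefact zeroing -> 30 Hz FIR low-pass.

#' IMU gating configuration
#'
#' The inertial measurement unit on the ultrasound probe records probe
#' motion; sensor samples coincident with probe motion are artefact and are
#' zeroed. The threshold applies to the raw (un-normalised) IMU magnitude,
#' whose quiescent level has unit variance, so the candidate integer
#' thresholds 4, 5 and 6 are absolute.
#'
#' @param imu_threshold Gate when `|imu|` exceeds this value (default 5, the
#'   best-performing of the candidates 4, 5, 6).
#' @param guard_s Seconds of additional zeroing either side of each
#'   threshold crossing (default 0: only coincident samples are zeroed).
#' @return An object of class `noise_cancel_config`.
#' @export
noise_cancel_config <- function(imu_threshold = 5, guard_s = 0) {
  stopifnot_scalar_pos(imu_threshold, "imu_threshold")
  if (guard_s < 0) stop("'guard_s' must be >= 0", call. = FALSE)
  structure(list(imu_threshold = imu_threshold, guard_s = guard_s),
            class = "noise_cancel_config")
}

#' Low-pass filter configuration
#'
#' Fetal movements carry energy below about 30 Hz, so everything above the
#' cutoff is out of scope. The filter is a linear-phase FIR designed with a
#' Kaiser window: passband edge at `cutoff_hz`, stopband edge 5 Hz above it,
#' 40 dB stopband attenuation, 0.5 dB passband ripple.
#'
#' @param cutoff_hz Passband edge in Hz (default 30).
#' @param fs Sampling rate in Hz (default 512).
#' @param transition_hz Width of the transition band in Hz (default 5).
#' @param stopband_db Minimum stopband attenuation in dB (default 40).
#' @param ripple_db Maximum passband ripple in dB (default 0.5).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(cutoff_hz = 30, fs = 512, transition_hz = 5,
                          stopband_db = 40, ripple_db = 0.5) {
  stopifnot_scalar_pos(cutoff_hz, "cutoff_hz")
  stopifnot_scalar_pos(fs, "fs")
  if (cutoff_hz + transition_hz >= fs / 2)
    stop("cutoff (plus transition band) must lie below the Nyquist frequency",
         call. = FALSE)
  structure(list(cutoff_hz = cutoff_hz, fs = fs, transition_hz = transition_hz,
                 stopband_db = stopband_db, ripple_db = ripple_db,
                 design = "fir-kaiser"),
            class = "filter_config")
}

#' Remove the constant offset of a signal
#'
#' Subtracts the signal mean, cancelling the sensor's inherent voltage
#' offset. Idempotent on zero-mean signals.
#' @param signal Numeric vector.
#' @return The zero-mean signal.
#' @export
remove_offset <- function(signal) {
  if (length(signal) == 0) stop("empty signal", call. = FALSE)
  signal - mean(signal)
}

#' Normalise a signal to unit RMS
#'
#' Divides by the root-mean-square value so channels of widely varying
#' amplitude become comparable.
#' @param signal Numeric vector with non-zero RMS.
#' @return The signal scaled to RMS 1.
#' @export
rms_normalise <- function(signal) {
  if (length(signal) == 0) stop("empty signal", call. = FALSE)
  r <- sqrt(mean(signal^2))
  if (r == 0) stop("zero RMS: degenerate (all-zero) channel", call. = FALSE)
  signal / r
}

# Boolean gate mask: |imu| above threshold, dilated by guard_s seconds.
gate_mask <- function(imu, config, fs = NULL) {
  m <- abs(imu) > config$imu_threshold
  if (config$guard_s > 0) {
    if (is.null(fs)) stop("'fs' needed when guard_s > 0", call. = FALSE)
    g <- round(config$guard_s * fs)
    if (g > 0 && any(m)) {
      idx <- which(m)
      ext <- unique(pmin(pmax(rep(idx, each = 2 * g + 1) + (-g):g, 1L), length(m)))
      m[ext] <- TRUE
    }
  }
  m
}

#' Zero sensor samples coincident with ultrasound-probe motion
#'
#' Every sample where the IMU magnitude exceeds the threshold (plus an
#' optional guard window) is set to zero in all sensor channels; all other
#' samples are unchanged. Idempotent.
#'
#' @param sensors Numeric matrix, samples in rows, one column per channel.
#' @param imu IMU magnitude vector, same number of samples.
#' @param config A [noise_cancel_config()].
#' @param fs Sampling rate; only required when `guard_s > 0`.
#' @return The gated sensor matrix.
#' @export
cancel_probe_noise <- function(sensors, imu, config = noise_cancel_config(),
                               fs = NULL) {
  if (!is.matrix(sensors)) sensors <- matrix(sensors, ncol = 1)
  if (nrow(sensors) != length(imu))
    stop("sensors and imu must share the sample count", call. = FALSE)
  m <- gate_mask(imu, config, fs)
  sensors[m, ] <- 0
  sensors
}

#' Synchronise a recording to the push-button time stamp
#'
#' The participant's push button is trial-pressed once at the start of each
#' session; its time stamp aligns the sensor clock with the ultrasound
#' annotations. The time origin is shifted so the first press is t = 0:
#' samples before it are dropped and all annotation onsets and MPM presses
#' are shifted identically. Annotations that fall before the sync press are
#' dropped with a warning.
#'
#' @param recording An `fm_recording` whose button channel contains a press.
#' @param track The matching `fm_track`.
#' @return A list with the shifted `recording` and `track`.
#' @export
synchronise <- function(recording, track) {
  press <- which(recording$button > 0)
  if (length(press) == 0L)
    stop("no sync press found on the button channel", call. = FALSE)
  i0 <- press[1]
  t0 <- (i0 - 1) / recording$fs
  if (i0 > 1L) {
    recording$sensors <- recording$sensors[-seq_len(i0 - 1L), , drop = FALSE]
    recording$imu <- recording$imu[-seq_len(i0 - 1L)]
    recording$button <- recording$button[-seq_len(i0 - 1L)]
  }
  ev <- track$events
  ev$onset_s <- ev$onset_s - t0
  drop <- ev$onset_s < 0
  if (any(drop)) {
    warning(sum(drop), " annotation event(s) before the sync press dropped")
    ev <- ev[!drop, , drop = FALSE]
  }
  track$events <- ev
  track$mpm_s <- track$mpm_s[track$mpm_s - t0 >= 0] - t0
  track$sync_press_s <- 0
  list(recording = recording, track = track)
}

#' Kaiser-window FIR low-pass coefficients
#'
#' Designs the linear-phase filter described by a [filter_config()] (order
#' forced even so the group delay is an integer number of samples). The
#' coefficient vector can be written to CSV for inspection.
#'
#' @param config A [filter_config()].
#' @return Numeric coefficient vector with attributes `order` and `beta`.
#' @export
lowpass_coefficients <- function(config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  dev <- c(10^(config$ripple_db / 20) - 1, 10^(-config$stopband_db / 20))
  ko <- signal::kaiserord(c(config$cutoff_hz, config$cutoff_hz + config$transition_hz),
                          c(1, 0), dev, config$fs)
  n <- ko$n + ko$n %% 2L
  h <- signal::fir1(n, ko$Wc, "low", signal::kaiser(n + 1, ko$beta))
  h <- as.numeric(h)
  attr(h, "order") <- n
  attr(h, "beta") <- ko$beta
  h
}

#' Apply the 30 Hz low-pass filter
#'
#' Single-pass linear-phase FIR with group-delay compensation (the output is
#' shifted back by half the filter order), so filtered samples stay aligned
#' with the annotation timeline.
#'
#' @param signal Numeric vector sampled at `config$fs`.
#' @param config A [filter_config()].
#' @param coefs Optional precomputed [lowpass_coefficients()] (saves
#'   repeated design when filtering many channels).
#' @return The filtered signal, same length as the input.
#' @export
lowpass <- function(signal, config = filter_config(), coefs = NULL) {
  if (is.null(coefs)) coefs <- lowpass_coefficients(config)
  d <- length(coefs) %/% 2L
  y <- as.numeric(signal::filter(coefs, 1, c(signal, numeric(d))))
  y[(d + 1):(d + length(signal))]
}

#' Run the full signal-cleaning chain
#'
#' Applies, in fixed order: [synchronise()], [remove_offset()] per channel,
#' [rms_normalise()] per channel, [cancel_probe_noise()] (on the raw IMU
#' magnitude), and [lowpass()] per channel. The IMU channel itself is left
#' untouched; the RMS is computed over the whole channel, including samples
#' later zeroed by the gate.
#'
#' @param recording An `fm_recording`.
#' @param track The matching `fm_track`.
#' @param noise_cfg A [noise_cancel_config()].
#' @param filter_cfg A [filter_config()]; its `fs` must match the recording.
#' @return A list with the cleaned `recording` and shifted `track`.
#' @export
preprocess_recording <- function(recording, track,
                                 noise_cfg = noise_cancel_config(),
                                 filter_cfg = filter_config(fs = recording$fs)) {
  if (!isTRUE(all.equal(filter_cfg$fs, recording$fs)))
    stop("filter_config fs does not match the recording", call. = FALSE)
  sync <- synchronise(recording, track)
  rec <- sync$recording
  for (k in seq_len(ncol(rec$sensors))) {
    ch <- rec$sensors[, k]
    ch <- remove_offset(ch)
    ch <- tryCatch(rms_normalise(ch),
                   error = function(e) stop("channel ", colnames(rec$sensors)[k],
                                            ": ", conditionMessage(e), call. = FALSE))
    rec$sensors[, k] <- ch
  }
  rec$sensors <- cancel_probe_noise(rec$sensors, rec$imu, noise_cfg, fs = rec$fs)
  coefs <- lowpass_coefficients(filter_cfg)
  for (k in seq_len(ncol(rec$sensors)))
    rec$sensors[, k] <- lowpass(rec$sensors[, k], filter_cfg, coefs)
  list(recording = rec, track = sync$track)
}
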