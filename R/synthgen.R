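# Synthetic session generator: annotated multichannel vibroacoustic recordings
# with the statistical structure the downstream analysis assumes.

#' Sensor channel names of the abdominal array
#'
#' Three piezoelectric (`PZ_*`) and three acoustic (`M_*`) contact sensors,
#' in the fixed array order used throughout the package.
#' @export
fm_channels <- function() c("PZ_a1", "PZ_a2", "M_a3", "M_a4", "M_a5", "PZ_a6")

fm_modalities <- function() c("piezo", "piezo", "acoustic", "acoustic", "acoustic", "piezo")

fm_event_classes <- function() c("general", "breathing", "startle", "limb")

#' Configuration for a synthetic scanning session
#'
#' Describes one ~30-minute ultrasound scanning session recorded by the
#' six-sensor abdominal array: session length, sampling rate, the expected
#' number and mix of fetal-movement events, how often the participant
#' perceives (and signals) a movement, and the probe-motion artefact model.
#'
#' Defaults reproduce the study conditions: 1800 s sessions sampled at
#' 512 Hz, about 240 one-second movement events (so roughly 13% of session
#' time is movement-active), and a 0.61 probability that an
#' ultrasound-detected movement is also maternally perceived.
#'
#' @param duration_s Session length in seconds.
#' @param fs Sampling rate in Hz.
#' @param event_rate Expected number of movement events per session. The
#'   default scales 240 events per 1800 s to `duration_s`.
#' @param event_duration_s Mean event duration in seconds (mixture mean over
#'   the four movement classes).
#' @param event_class_mix Named probabilities over the four movement classes
#'   `general`, `breathing`, `startle`, `limb`; must sum to 1.
#' @param perception_prob Probability that an event triggers a maternal
#'   push-button press within 0--2 s of its onset.
#' @param probe_rate Expected number of probe-motion artefact episodes per
#'   1800 s, scaled to `duration_s`.
#' @param probe_duration_range Episode duration range in seconds.
#' @param probe_amp_range IMU magnitude range during an episode, in units of
#'   the quiescent IMU noise standard deviation (unit variance at rest), so
#'   that integer gating thresholds of 4--6 are meaningful.
#' @param sensor_gains Per-channel scale applied to signal content (events
#'   and artefact bursts).
#' @param sensor_noise_sd Per-channel baseline noise standard deviation.
#' @param sensor_offsets Per-channel constant voltage offset (makes offset
#'   removal non-trivial).
#' @param seed Integer seed; every stochastic component derives an
#'   independent substream from it, so channel k is reproducible regardless
#'   of how many channels are generated.
#' @return An object of class `session_config`.
#' @export
session_config <- function(duration_s = 1800, fs = 512,
                           event_rate = 240 * duration_s / 1800,
                           event_duration_s = 1.0,
                           event_class_mix = c(general = 0.4, breathing = 0.3,
                                               startle = 0.1, limb = 0.2),
                           perception_prob = 0.61,
                           probe_rate = 15,
                           probe_duration_range = c(0.5, 3),
                           probe_amp_range = c(4, 8),
                           sensor_gains = c(1.0, 0.8, 1.2, 0.9, 1.1, 0.7),
                           sensor_noise_sd = c(0.50, 0.60, 0.40, 0.50, 0.45, 0.55),
                           sensor_offsets = c(0.5, -0.3, 0.2, -0.4, 0.1, 0.6),
                           seed = 1L) {
  stopifnot_scalar_pos(duration_s, "duration_s")
  stopifnot_scalar_pos(fs, "fs")
  if (event_rate < 0) stop("'event_rate' must be non-negative", call. = FALSE)
  stopifnot_scalar_pos(event_duration_s, "event_duration_s")
  if (perception_prob < 0 || perception_prob > 1)
    stop("'perception_prob' must lie in [0, 1]", call. = FALSE)
  cls <- fm_event_classes()
  if (is.null(names(event_class_mix))) names(event_class_mix) <- cls
  event_class_mix <- event_class_mix[cls]
  if (anyNA(event_class_mix) || abs(sum(event_class_mix) - 1) > 1e-8)
    stop("'event_class_mix' must be probabilities over the four classes summing to 1",
         call. = FALSE)
  if (length(sensor_gains) != 6L || length(sensor_noise_sd) != 6L ||
      length(sensor_offsets) != 6L)
    stop("per-channel parameters must have length 6", call. = FALSE)
  structure(list(
    duration_s = duration_s, fs = fs, n_sensors = 6L,
    modalities = fm_modalities(),
    event_rate = event_rate, event_duration_s = event_duration_s,
    event_class_mix = event_class_mix, perception_prob = perception_prob,
    probe_rate = probe_rate, probe_duration_range = probe_duration_range,
    probe_amp_range = probe_amp_range,
    sensor_gains = sensor_gains, sensor_noise_sd = sensor_noise_sd,
    sensor_offsets = sensor_offsets, seed = as.integer(seed)
  ), class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat("Synthetic session config:", x$duration_s, "s at", x$fs, "Hz;",
      format(x$event_rate, digits = 4), "expected events of",
      x$event_duration_s, "s (expected active fraction",
      format(expected_active_fraction(x), digits = 3), ")\n")
  invisible(x)
}

#' Expected movement-active fraction of a session
#'
#' Bookkeeping identity: expected events x mean event duration / session
#' length. At the defaults this is 240 x 1 s / 1800 s = 0.1333, i.e. about
#' 13% of session time carries movement.
#' @param config A [session_config()].
#' @return Expected fraction of annotated-active time.
#' @export
expected_active_fraction <- function(config) {
  config$event_rate * config$event_duration_s / config$duration_s
}

# Per-class duration multipliers (normalised against the class mix so the
# mixture mean equals event_duration_s) and burst amplitudes. Startle events
# are short and large, breathing long and small.
class_params <- function(config) {
  mult <- c(general = 1.0, breathing = 1.4, startle = 0.4, limb = 0.8)
  mult <- mult / sum(config$event_class_mix * mult)
  amp <- c(general = 4, breathing = 2, startle = 8, limb = 3)
  list(dur_mean = mult * config$event_duration_s, amp = amp)
}

#' Generate the annotation track of a synthetic session
#'
#' Draws the ultrasound-detected fetal movement (UDFM) events — count,
#' classes, durations, non-overlapping onsets — plus the maternally
#' perceived movement (MPM) push-button presses (each event perceived with
#' probability `perception_prob`, pressed 0--2 s after onset) and the sync
#' press near session start. Deterministic given `config$seed`.
#'
#' @param config A [session_config()].
#' @param scan_id Identifier stored on the track.
#' @return An object of class `fm_track`: a list with `events`
#'   (data frame: `onset_s`, `duration_s`, `class`, `perceived`), `mpm_s`
#'   (press times), `sync_press_s` and `scan_id`.
#' @export
generate_annotations <- function(config, scan_id = "scan01") {
  stopifnot(inherits(config, "session_config"))
  cp <- class_params(config)
  dur <- config$duration_s
  sync_s <- with_seed(substream(config$seed, 3L),
                      runif(1, 0.05, 0.25) * min(dur, 60))

  ev <- with_seed(substream(config$seed, 1L), {
    n <- rpois(1, config$event_rate)
    if (n == 0L) {
      data.frame(onset_s = numeric(0), duration_s = numeric(0),
                 class = character(0), perceived = logical(0),
                 stringsAsFactors = FALSE)
    } else {
      cls <- sample(fm_event_classes(), n, replace = TRUE,
                    prob = config$event_class_mix)
      # gamma durations: shape 6 keeps them positive with mild spread
      d <- rgamma(n, shape = 6, rate = 6 / cp$dur_mean[cls])
      lo <- min(16, 0.3 * dur)
      onset <- rep(NA_real_, n)
      placed <- cbind(numeric(0), numeric(0))
      for (i in seq_len(n)) {
        hi <- dur - d[i]
        if (hi <= lo) next
        for (try in 1:80) {
          o <- runif(1, lo, hi)
          if (!any(o < placed[, 2] & o + d[i] > placed[, 1])) {
            onset[i] <- o
            placed <- rbind(placed, c(o, o + d[i]))
            break
          }
        }
      }
      keep <- !is.na(onset)
      out <- data.frame(onset_s = onset[keep], duration_s = d[keep],
                        class = cls[keep], stringsAsFactors = FALSE)
      out <- out[order(out$onset_s), , drop = FALSE]
      rownames(out) <- NULL
      out
    }
  })

  ev$perceived <- with_seed(substream(config$seed, 2L),
                            rbinom(nrow(ev), 1, config$perception_prob) == 1L)
  mpm <- with_seed(substream(config$seed, 4L), {
    if (any(ev$perceived))
      pmin(ev$onset_s[ev$perceived] + runif(sum(ev$perceived), 0, 2), dur - 0.05)
    else numeric(0)
  })

  structure(list(events = ev, mpm_s = sort(mpm), sync_press_s = sync_s,
                 scan_id = scan_id), class = "fm_track")
}

#' @export
print.fm_track <- function(x, ...) {
  cat("Annotation track", x$scan_id, ":", nrow(x$events), "UDFM events (",
      sum(x$events$perceived), "perceived ),", length(x$mpm_s),
      "MPM presses, sync at", format(x$sync_press_s, digits = 4), "s\n")
  invisible(x)
}

# Hann^2-windowed damped sinusoid packet; compact support and energy
# concentrated around the carrier (1-25 Hz), i.e. below the 30 Hz band edge.
event_burst <- function(tt, dur, carrier_hz, phase, amp, breathing = FALSE) {
  env <- sin(pi * tt / dur)^2 * exp(-2 * tt / dur)
  b <- amp * env * sin(2 * pi * carrier_hz * tt + phase)
  if (breathing) b <- b * (1 + 0.6 * sin(2 * pi * 1.0 * tt))
  b
}

#' Generate a synthetic annotated recording
#'
#' Produces one session of the six-channel vibroacoustic array plus IMU and
#' push-button channels, together with its annotation track. Movement events
#' are band-limited damped-sinusoid packets (carrier 1--25 Hz) added to every
#' sensor channel with modality-dependent attenuation and a random per-event
#' per-sensor emphasis; each channel carries Gaussian baseline noise with a
#' channel-specific constant offset; probe-motion episodes add broadband
#' bursts to the sensor channels exactly where the IMU channel is raised
#' above its quiescent (unit-variance) level; the button channel carries one
#' sync press in the first 30 s and one press per perceived event. The
#' output is bit-reproducible given `config$seed`.
#'
#' @param config A [session_config()].
#' @param scan_id,subject_id,gestation_weeks Metadata stored on the recording.
#' @return A list with components `recording` (class `fm_recording`: sensor
#'   matrix `[n_samples x 6]` with channels named per [fm_channels()], `imu`,
#'   `button`, `fs` and metadata) and `track` (class `fm_track`).
#' @export
generate_recording <- function(config, scan_id = "scan01",
                               subject_id = "subj01", gestation_weeks = 34) {
  stopifnot(inherits(config, "session_config"))
  track <- generate_annotations(config, scan_id)
  n <- round(config$duration_s * config$fs)
  fs <- config$fs

  sensors <- matrix(0, n, 6L, dimnames = list(NULL, fm_channels()))
  for (k in 1:6)
    sensors[, k] <- with_seed(substream(config$seed, 10L + k),
                              rnorm(n, 0, config$sensor_noise_sd[k])) +
      config$sensor_offsets[k]

  imu <- with_seed(substream(config$seed, 20L), rnorm(n))

  # probe-motion artefact episodes, co-registered on the IMU channel
  probe <- with_seed(substream(config$seed, 21L), {
    n_ep <- rpois(1, config$probe_rate * config$duration_s / 1800)
    if (n_ep == 0L) NULL else {
      d <- runif(n_ep, config$probe_duration_range[1], config$probe_duration_range[2])
      s <- runif(n_ep, 0, pmax(0, config$duration_s - d))
      a <- runif(n_ep, config$probe_amp_range[1], config$probe_amp_range[2])
      lapply(seq_len(n_ep), function(i) {
        i0 <- floor(s[i] * fs) + 1L
        i1 <- min(n, i0 + max(1L, round(d[i] * fs)) - 1L)
        idx <- i0:i1
        list(idx = idx,
             imu = pmax(a[i] + 0.3 * rnorm(length(idx)), 3.6),
             burst = matrix(rnorm(length(idx) * 6L, 0, 3), ncol = 6L))
      })
    }
  })
  if (!is.null(probe)) {
    for (ep in probe) {
      imu[ep$idx] <- ep$imu
      sensors[ep$idx, ] <- sensors[ep$idx, ] +
        ep$burst * rep(config$sensor_gains, each = length(ep$idx))
    }
  }

  # movement events
  cp <- class_params(config)
  modality_gain <- ifelse(config$modalities == "piezo", 1.0, 0.7)
  with_seed(substream(config$seed, 30L), {
    ev <- track$events
    for (i in seq_len(nrow(ev))) {
      i0 <- floor(ev$onset_s[i] * fs) + 1L
      len <- max(2L, round(ev$duration_s[i] * fs))
      i1 <- min(n, i0 + len - 1L)
      tt <- (seq.int(i0, i1) - i0) / fs
      carrier <- runif(1, 1, 25)
      phase <- runif(1, 0, 2 * pi)
      amp <- cp$amp[ev$class[i]] * exp(rnorm(1, 0, 0.2))
      w <- modality_gain * exp(rnorm(6, 0, 0.4))
      b <- event_burst(tt, ev$duration_s[i], carrier, phase, amp,
                       breathing = ev$class[i] == "breathing")
      sensors[i0:i1, ] <- sensors[i0:i1, ] +
        outer(b, config$sensor_gains * w)
    }
  })

  button <- numeric(n)
  press_len <- max(1L, round(0.2 * fs))
  for (p in c(track$sync_press_s, track$mpm_s)) {
    i0 <- floor(p * fs) + 1L
    button[i0:min(n, i0 + press_len - 1L)] <- 1
  }

  recording <- structure(list(
    sensors = sensors, imu = imu, button = button, fs = fs,
    subject_id = subject_id, scan_id = scan_id,
    gestation_weeks = gestation_weeks
  ), class = "fm_recording")
  list(recording = recording, track = track)
}

#' @export
print.fm_recording <- function(x, ...) {
  cat("Vibroacoustic recording", x$scan_id, ":", nrow(x$sensors),
      "samples x", ncol(x$sensors), "sensors at", x$fs, "Hz (",
      format(nrow(x$sensors) / x$fs, digits = 5), "s )\n")
  invisible(x)
}

# Validate track invariants; used by read_recording and synchronise.
validate_track <- function(track, duration_s = NULL) {
  ev <- track$events
  if (nrow(ev) > 0) {
    if (is.unsorted(ev$onset_s))
      stop("annotation events must be sorted by onset", call. = FALSE)
    if (any(ev$onset_s < 0))
      stop("annotation events must have non-negative onsets", call. = FALSE)
    if (!is.null(duration_s) && any(ev$onset_s + ev$duration_s > duration_s + 1e-9))
      stop("annotation events must end within the session", call. = FALSE)
    if (nrow(ev) > 1) {
      ends <- ev$onset_s + ev$duration_s
      if (any(ev$onset_s[-1] < ends[-nrow(ev)] - 1e-12))
        stop("annotation events must not overlap", call. = FALSE)
    }
  }
  invisible(track)
}
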