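# Columnar CSV + JSON sidecar serialisation of recordings and annotations.
#
# Schema: <stem>.csv has columns t, PZ_a1, PZ_a2, M_a3, M_a4, M_a5, PZ_a6,
# IMU, BUTTON (one row per sample); <stem>.json carries scan metadata, the
# UDFM event list, MPM press times and the sync press time.

#' Write a recording and its annotation track to disk
#'
#' Emits a columnar CSV (one row per sample; columns `t`, the six sensor
#' channels of [fm_channels()], `IMU`, `BUTTON`) and a JSON annotation
#' sidecar. The pair round-trips losslessly (to float printing precision)
#' through [read_recording()].
#'
#' @param recording An `fm_recording`.
#' @param track The matching `fm_track`.
#' @param path Output stem; `<path>.csv` and `<path>.json` are written.
#' @return Invisibly, the two file paths written.
#' @export
write_recording <- function(recording, track, path) {
  stopifnot(inherits(recording, "fm_recording"), inherits(track, "fm_track"))
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  n <- nrow(recording$sensors)
  dt <- data.table::data.table(t = (seq_len(n) - 1) / recording$fs)
  for (ch in fm_channels()) dt[[ch]] <- recording$sensors[, ch]
  dt[["IMU"]] <- recording$imu
  dt[["BUTTON"]] <- recording$button
  data.table::fwrite(dt, csv)

  ev <- track$events
  meta <- list(
    scan_id = track$scan_id,
    subject_id = recording$subject_id,
    gestation_weeks = recording$gestation_weeks,
    fs = recording$fs,
    sync_press_s = track$sync_press_s,
    mpm_press_s = as.numeric(track$mpm_s),
    events = lapply(seq_len(nrow(ev)), function(i) list(
      onset_s = ev$onset_s[i], duration_s = ev$duration_s[i],
      class = ev$class[i], perceived = ev$perceived[i]))
  )
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}

#' Read a recording and annotation track written by [write_recording()]
#'
#' Validates the documented schema and the session invariants: exactly six
#' sensor channels, a sync press within the first 30 s, sorted
#' non-overlapping events ending inside the session.
#'
#' @param path File stem as passed to [write_recording()].
#' @return A list with `recording` (`fm_recording`) and `track` (`fm_track`).
#' @export
read_recording <- function(path) {
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  if (!file.exists(csv) || !file.exists(json))
    stop("missing recording files at stem '", path, "'", call. = FALSE)
  dt <- data.table::fread(csv)
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)

  want <- c("t", fm_channels(), "IMU", "BUTTON")
  sensor_cols <- setdiff(names(dt), c("t", "IMU", "BUTTON"))
  if (length(sensor_cols) != 6L)
    stop("expected 6 sensor channels, found ", length(sensor_cols), call. = FALSE)
  if (!identical(names(dt), want))
    stop("recording CSV columns must be exactly: ", paste(want, collapse = ", "),
         call. = FALSE)

  fs <- meta$fs
  n <- nrow(dt)
  sensors <- as.matrix(dt[, fm_channels(), with = FALSE])
  recording <- structure(list(
    sensors = sensors, imu = dt[["IMU"]], button = dt[["BUTTON"]], fs = fs,
    subject_id = meta$subject_id %||% NA_character_,
    scan_id = meta$scan_id %||% NA_character_,
    gestation_weeks = meta$gestation_weeks %||% NA_real_
  ), class = "fm_recording")

  ev <- meta$events
  if (is.null(ev) || (is.data.frame(ev) && nrow(ev) == 0) || length(ev) == 0) {
    ev <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                     class = character(0), perceived = logical(0),
                     stringsAsFactors = FALSE)
  } else {
    ev <- as.data.frame(ev, stringsAsFactors = FALSE)
    ev$perceived <- as.logical(ev$perceived)
  }
  track <- structure(list(events = ev,
                          mpm_s = as.numeric(meta$mpm_press_s),
                          sync_press_s = meta$sync_press_s,
                          scan_id = meta$scan_id %||% NA_character_),
                     class = "fm_track")

  press <- which(recording$button > 0)
  if (length(press) == 0L || (press[1] - 1) / fs > 30)
    stop("button channel must contain a sync press within the first 30 s",
         call. = FALSE)
  validate_track(track, duration_s = n / fs)
  list(recording = recording, track = track)
}
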