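# Orchestration: config-driven simulation, experiment runs and searches with
# a reproducibility manifest per output directory.

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path", call. = FALSE)
  config
}

session_config_from <- function(cfg, seed) {
  known <- setdiff(names(formals(session_config)), "seed")
  given <- cfg[intersect(names(cfg), known)]
  missing <- setdiff(c("duration_s", "fs"), names(given))
  if (length(missing))
    message("config fields ", paste(missing, collapse = ", "),
            " not given; defaults applied")
  do.call(session_config, c(given, list(seed = seed)))
}

write_manifest <- function(out_dir, config, seed, outputs) {
  paths <- file.path(out_dir, outputs)
  manifest <- list(
    package = "fetalmove",
    version = as.character(utils::packageVersion("fetalmove")),
    created = format(Sys.time(), tz = "UTC"),
    seed = seed,
    config = config,
    outputs = lapply(seq_along(outputs), function(i) list(
      file = outputs[i], md5 = unname(tools::md5sum(paths[i]))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a batch of annotated scans to disk
#'
#' Generates `n_scans` synthetic sessions (seeded per scan from `seed`) and
#' writes each as the CSV + JSON pair of [write_recording()], plus a
#' `manifest.json` recording the config, seed, package version and file
#' hashes. Re-running with the same config and seed reproduces byte-identical
#' data files.
#'
#' @param config A list (or YAML/JSON file path) of [session_config()]
#'   fields plus optional `n_scans` and `seed`; missing fields take the
#'   defaults (with a message).
#' @param out_dir Output directory (created if needed).
#' @param n_scans,seed Override the config values.
#' @return Invisibly, the scan file stems written.
#' @export
fm_simulate <- function(config = list(), out_dir, n_scans = NULL, seed = NULL) {
  config <- load_config(config)
  n_scans <- n_scans %||% config$n_scans %||% 1L
  seed <- seed %||% config$seed %||% 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stems <- character(n_scans)
  outputs <- character(0)
  for (i in seq_len(n_scans)) {
    sc <- session_config_from(config, substream(seed, i))
    id <- sprintf("scan%02d", i)
    g <- generate_recording(sc, scan_id = id,
                            subject_id = sprintf("subj%02d", i))
    stems[i] <- file.path(out_dir, id)
    write_recording(g$recording, g$track, stems[i])
    outputs <- c(outputs, paste0(id, ".csv"), paste0(id, ".json"))
  }
  write_manifest(out_dir, config, seed, outputs)
  invisible(stems)
}

read_scan_dir <- function(data_dir) {
  csvs <- sort(list.files(data_dir, pattern = "\\.csv$", full.names = TRUE))
  stems <- sub("\\.csv$", "", csvs)
  stems <- stems[file.exists(paste0(stems, ".json"))]
  if (length(stems) == 0) stop("no recordings found in ", data_dir, call. = FALSE)
  loaded <- lapply(stems, read_recording)
  list(recordings = lapply(loaded, `[[`, "recording"),
       tracks = lapply(loaded, `[[`, "track"))
}

#' Run detection experiments over recorded scans
#'
#' Reads every recording in `data_dir`, runs [run_experiment()] for each
#' requested `(model_input, classifier)` cell and writes a results table
#' (`results.csv`: one row per cell with precision/recall/F1/specificity/
#' accuracy), the per-scan confusion counts (`per_scan.csv`) and a
#' manifest. Scans that fail a cell are skipped with a warning and listed
#' in the manifest.
#'
#' @param config List (or YAML/JSON path) with optional `model_inputs`
#'   (default `1:3`), `classifier` (default `"rusboost"`),
#'   `classifier_args`, `train_fraction`, `imu_threshold`, spectral fields
#'   `window_s`/`overlap_s`, and `seed`.
#' @param data_dir Directory of [fm_simulate()]-style scan files.
#' @param out_dir Output directory.
#' @param seed Overrides the config seed.
#' @return Invisibly, the results data frame.
#' @export
fm_run <- function(config = list(), data_dir, out_dir, seed = NULL) {
  config <- load_config(config)
  seed <- seed %||% config$seed %||% 1L
  dat <- read_scan_dir(data_dir)
  fs <- dat$recordings[[1]]$fs
  model_inputs <- config$model_inputs %||% 1:3
  classifiers <- config$classifier %||% "rusboost"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  rows <- list(); per_scan <- list(); skipped <- character(0)
  for (cl in classifiers) for (mi in model_inputs) {
    cfg <- experiment_config(
      model_input = mi, classifier = cl,
      train_fraction = config$train_fraction %||% 0.7,
      noise_cfg = noise_cancel_config(config$imu_threshold %||% 5),
      spectral_cfg = spectral_config(config$window_s %||% 8,
                                     config$overlap_s %||% 2, fs = fs),
      classifier_args = config$classifier_args %||% list(),
      seed = seed)
    rep <- tryCatch(run_experiment(dat$recordings, dat$tracks, cfg),
                    error = function(e) {
                      warning("cell (input ", mi, ", ", cl, ") failed: ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(rep)) { skipped <- c(skipped, paste(mi, cl)); next }
    m <- rep$metrics
    rows[[length(rows) + 1L]] <- data.frame(
      model_input = mi, classifier = cl,
      precision = m$precision, recall = m$recall, f1 = m$f1,
      specificity = m$specificity, accuracy = m$accuracy)
    ps <- rep$per_scan
    ps$model_input <- mi; ps$classifier <- cl
    per_scan[[length(per_scan) + 1L]] <- ps
  }
  results <- do.call(rbind, rows)
  data.table::fwrite(results, file.path(out_dir, "results.csv"))
  data.table::fwrite(do.call(rbind, per_scan), file.path(out_dir, "per_scan.csv"))
  config$skipped <- if (length(skipped)) skipped else NULL
  write_manifest(out_dir, config, seed, c("results.csv", "per_scan.csv"))
  invisible(results)
}

#' IMU-threshold and STFT grid searches over recorded scans
#'
#' Wraps [imu_threshold_search()] and/or [stft_grid_search()] over the
#' scans in `data_dir`, writing each search table (with the selected
#' parameters flagged) and a manifest.
#'
#' @param config List (or YAML/JSON path); recognised fields:
#'   `imu_thresholds` (default `c(4, 5, 6)`), `windows`, `overlaps`
#'   (defaults 2--10 and 1--4), plus the [fm_run()] experiment fields.
#' @param data_dir Directory of scan files.
#' @param out_dir Output directory.
#' @param searches Which searches to run, subset of `c("imu", "stft")`.
#' @param seed Overrides the config seed.
#' @return Invisibly, a list of the search tables.
#' @export
fm_search <- function(config = list(), data_dir, out_dir,
                      searches = c("imu", "stft"), seed = NULL) {
  config <- load_config(config)
  seed <- seed %||% config$seed %||% 1L
  dat <- read_scan_dir(data_dir)
  fs <- dat$recordings[[1]]$fs
  cfg <- experiment_config(
    model_input = config$model_input %||% 2L,
    classifier = config$classifier %||% "rusboost",
    train_fraction = config$train_fraction %||% 0.7,
    spectral_cfg = spectral_config(config$window_s %||% 8,
                                   config$overlap_s %||% 2, fs = fs),
    classifier_args = config$classifier_args %||% list(),
    seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  out <- list(); outputs <- character(0)
  if ("imu" %in% searches) {
    tab <- imu_threshold_search(dat$recordings, dat$tracks,
                                config$imu_thresholds %||% c(4, 5, 6), cfg)
    tab$selected <- tab$threshold == attr(tab, "best")
    data.table::fwrite(tab, file.path(out_dir, "imu_search.csv"))
    outputs <- c(outputs, "imu_search.csv")
    out$imu <- tab
  }
  if ("stft" %in% searches) {
    tab <- stft_grid_search(dat$recordings, dat$tracks,
                            config$windows %||% 2:10,
                            config$overlaps %||% 1:4, cfg)
    best <- attr(tab, "best")
    tab$selected <- tab$window_s == best$window_s &
      tab$overlap_s == best$overlap_s
    data.table::fwrite(tab, file.path(out_dir, "stft_search.csv"))
    outputs <- c(outputs, "stft_search.csv")
    out$stft <- tab
  }
  write_manifest(out_dir, config, seed, outputs)
  invisible(out)
}

#' Maternal-perception agreement over recorded scans
#'
#' Computes [mpm_vs_udfm_agreement()] for every scan in `data_dir` and
#' writes a per-scan table plus a manifest.
#'
#' @param data_dir Directory of scan files.
#' @param out_dir Output directory.
#' @param window_s Discretisation window in seconds.
#' @return Invisibly, the agreement data frame.
#' @export
fm_agreement <- function(data_dir, out_dir, window_s = 8) {
  dat <- read_scan_dir(data_dir)
  rows <- lapply(seq_along(dat$tracks), function(i) {
    dur <- nrow(dat$recordings[[i]]$sensors) / dat$recordings[[i]]$fs
    a <- mpm_vs_udfm_agreement(dat$tracks[[i]], window_s, dur)
    data.frame(scan_id = dat$tracks[[i]]$scan_id,
               n_events = attr(a, "n_events"),
               accuracy = a$accuracy, precision = a$precision,
               recall = a$recall, specificity = a$specificity)
  })
  out <- do.call(rbind, rows)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(out, file.path(out_dir, "agreement.csv"))
  write_manifest(out_dir, list(window_s = window_s), NA, "agreement.csv")
  invisible(out)
}
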