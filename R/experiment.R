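# The experiment protocol: full pipeline per scan (preprocess -> STFT ->
# fusion -> chronological 70/30 split -> fit -> predict -> confusion), the
# matching cross-scan aggregation, and the two hyperparameter searches.

#' Experiment configuration
#'
#' Bundles every knob of one detection experiment: the fusion strategy
#' (`model_input` 1 = per-sensor, 2 = concatenated, 3 = summed), the
#' classifier and its settings, the preprocessing and spectral configs, the
#' training fraction and the seed.
#'
#' @param model_input 1, 2 or 3.
#' @param classifier `"knn"`, `"tree"`, `"adaboost"` or `"rusboost"`.
#' @param train_fraction Chronological training fraction (default 0.7).
#' @param noise_cfg A [noise_cancel_config()].
#' @param spectral_cfg A [spectral_config()].
#' @param classifier_args Named list of extra arguments for the classifier
#'   constructor (e.g. `list(n_estimators = 50)`).
#' @param seed Integer seed for the stochastic classifiers.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(model_input = 2L,
                              classifier = c("rusboost", "adaboost", "tree", "knn"),
                              train_fraction = 0.7,
                              noise_cfg = noise_cancel_config(),
                              spectral_cfg = spectral_config(),
                              classifier_args = list(),
                              seed = 1L) {
  classifier <- match.arg(classifier)
  if (!model_input %in% 1:3) stop("'model_input' must be 1, 2 or 3", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("'train_fraction' must lie in (0, 1)", call. = FALSE)
  structure(list(model_input = as.integer(model_input), classifier = classifier,
                 train_fraction = train_fraction, noise_cfg = noise_cfg,
                 spectral_cfg = spectral_cfg, classifier_args = classifier_args,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# Fit the configured classifier on a training dataset and predict the test
# windows. Degenerate single-class training data falls back to a constant
# (majority-class) predictor with a warning so runs on sparse scans complete.
fit_and_predict <- function(train, test, config, seed) {
  args <- config$classifier_args
  if (length(unique(train$y)) < 2L && config$classifier != "knn") {
    warning("single-class training window set; using constant predictor")
    return(rep(train$y[1], nrow(test$X)))
  }
  model <- switch(config$classifier,
    knn = do.call(fm_knn, c(list(train$X, train$y,
                                 k = min(args$k %||% 3L, nrow(train$X))),
                            args[setdiff(names(args), "k")])),
    tree = do.call(fm_tree, c(list(train$X, train$y), args)),
    adaboost = do.call(fm_adaboost, c(list(train$X, train$y), args)),
    rusboost = do.call(fm_rusboost, c(list(train$X, train$y, seed = seed),
                                      args[setdiff(names(args), "seed")])))
  predict(model, test$X)
}

# One scan through the full pipeline; returns the confusion counts for the
# configured fusion strategy (a list of 6 for model input 1).
scan_confusions <- function(recording, track, config, scan_seed) {
  pp <- preprocess_recording(recording, track, config$noise_cfg,
                             filter_config(fs = recording$fs))
  sc <- config$spectral_cfg
  if (!isTRUE(all.equal(sc$fs, recording$fs)))
    sc <- spectral_config(sc$window_s, sc$overlap_s, recording$fs, sc$max_freq_hz)
  specs <- lapply(seq_len(ncol(pp$recording$sensors)), function(k)
    compute_stft(pp$recording$sensors[, k], sc,
                 colnames(pp$recording$sensors)[k]))
  y <- label_windows(specs[[1]]$window_starts_s, sc, pp$track)

  eval_one <- function(ds, sub) {
    sp <- split_train_test(ds, config$train_fraction)
    pred <- fit_and_predict(sp$train, sp$test, config, substream(scan_seed, sub))
    confusion(sp$test$y, pred)
  }
  if (config$model_input == 1L) {
    dss <- fuse_individual(specs, y, recording$scan_id)
    lapply(seq_along(dss), function(k) eval_one(dss[[k]], k))
  } else if (config$model_input == 2L) {
    eval_one(fuse_concatenated(specs, y, recording$scan_id), 1L)
  } else {
    eval_one(fuse_summed(specs, y, recording$scan_id), 1L)
  }
}

#' Run a detection experiment over a set of scans
#'
#' For every scan: clean the recording, compute the six spectrograms, build
#' the configured fusion dataset, split chronologically, fit the classifier
#' on the training windows, predict the held-out windows and tally the
#' confusion counts. Counts are then averaged with the scheme matching the
#' fusion strategy ([aggregate_model1()] for per-sensor analysis,
#' [aggregate_model23()] otherwise).
#'
#' @param recordings List of `fm_recording`.
#' @param tracks Matching list of `fm_track`.
#' @param config An [experiment_config()].
#' @return An object of class `fm_report`: `metrics`, averaged `counts`, a
#'   `per_scan` data frame of counts (per sensor for model input 1), and
#'   the config.
#' @export
run_experiment <- function(recordings, tracks, config = experiment_config()) {
  stopifnot(length(recordings) == length(tracks), length(recordings) >= 1L)
  per_scan <- lapply(seq_along(recordings), function(i)
    scan_confusions(recordings[[i]], tracks[[i]], config,
                    substream(config$seed, i)))
  agg <- if (config$model_input == 1L) aggregate_model1(per_scan)
         else aggregate_model23(per_scan)

  rows <- list()
  for (i in seq_along(per_scan)) {
    cs <- if (config$model_input == 1L) per_scan[[i]] else per_scan[i]
    ids <- if (config$model_input == 1L) fm_channels() else "all"
    for (k in seq_along(cs))
      rows[[length(rows) + 1L]] <- data.frame(
        scan_id = recordings[[i]]$scan_id, sensor_id = ids[k],
        tp = cs[[k]]$tp, tn = cs[[k]]$tn, fp = cs[[k]]$fp, fn = cs[[k]]$fn,
        stringsAsFactors = FALSE)
  }
  structure(list(metrics = agg$metrics, counts = agg$counts,
                 per_scan = do.call(rbind, rows), config = config),
            class = "fm_report")
}

#' @export
print.fm_report <- function(x, ...) {
  cat("Detection experiment: model input", x$config$model_input,
      "/", x$config$classifier, "on",
      length(unique(x$per_scan$scan_id)), "scan(s)\n")
  print(x$metrics)
  invisible(x)
}

#' @export
summary.fm_report <- function(object, ...) {
  print(object)
  cat("\nAveraged confusion counts:\n")
  print(object$counts)
  invisible(object)
}

#' @export
plot.fm_report <- function(x, ...) {
  v <- unlist(x$metrics)[c("precision", "recall", "f1")]
  graphics::barplot(v, ylim = c(0, 1), ylab = "score",
                    main = paste("Model input", x$config$model_input, "-",
                                 x$config$classifier), ...)
  invisible(x)
}

#' IMU gating-threshold search
#'
#' Runs the experiment on the single scan with the most ultrasound-detected
#' events, once per candidate threshold, and reports precision and recall
#' per threshold. The selected threshold maximises the arithmetic mean of
#' precision and recall.
#'
#' @param recordings,tracks Scan set.
#' @param thresholds Candidate IMU magnitudes (default 4, 5, 6).
#' @param config Base [experiment_config()]; its `noise_cfg` threshold is
#'   overridden per candidate.
#' @return Data frame `(threshold, precision, recall)` with attribute
#'   `best` (the selected threshold).
#' @export
imu_threshold_search <- function(recordings, tracks, thresholds = c(4, 5, 6),
                                 config = experiment_config()) {
  n_ev <- vapply(tracks, function(t) nrow(t$events), 0L)
  i <- which.max(n_ev)
  rows <- lapply(thresholds, function(th) {
    cfg <- config
    cfg$noise_cfg <- noise_cancel_config(th, config$noise_cfg$guard_s)
    rep <- run_experiment(recordings[i], tracks[i], cfg)
    data.frame(threshold = th, precision = rep$metrics$precision,
               recall = rep$metrics$recall)
  })
  out <- do.call(rbind, rows)
  score <- (out$precision + out$recall) / 2
  attr(out, "best") <- out$threshold[which.max(score)]
  out
}

#' Valid STFT grid-search pairs
#'
#' All `(window_s, overlap_s)` combinations with `overlap < window`.
#' @param windows Candidate window lengths in seconds.
#' @param overlaps Candidate overlaps in seconds.
#' @return Data frame `(window_s, overlap_s)`.
#' @export
stft_grid_pairs <- function(windows = 2:10, overlaps = 1:4) {
  g <- expand.grid(window_s = windows, overlap_s = overlaps)
  g <- g[g$overlap_s < g$window_s, ]
  g <- g[order(g$window_s, g$overlap_s), ]
  rownames(g) <- NULL
  g
}

#' STFT window/overlap grid search
#'
#' Evaluates the experiment once per valid `(window, overlap)` pair and
#' selects the pair with the highest F1; ties break toward the larger
#' window, then the smaller overlap.
#'
#' @param recordings,tracks Scan set.
#' @param windows,overlaps Candidate grids in seconds (defaults 2--10 and
#'   1--4); invalid pairs (`overlap >= window`) are skipped.
#' @param config Base [experiment_config()]; its `spectral_cfg` is
#'   overridden per pair.
#' @return Data frame `(window_s, overlap_s, f1)` with attribute `best`
#'   (a list with the selected `window_s` and `overlap_s`).
#' @export
stft_grid_search <- function(recordings, tracks, windows = 2:10,
                             overlaps = 1:4, config = experiment_config()) {
  grid <- stft_grid_pairs(windows, overlaps)
  if (nrow(grid) == 0) stop("no valid (window, overlap) pairs", call. = FALSE)
  f1 <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$spectral_cfg <- spectral_config(grid$window_s[i], grid$overlap_s[i],
                                        config$spectral_cfg$fs,
                                        config$spectral_cfg$max_freq_hz)
    rep <- run_experiment(recordings, tracks, cfg)
    rep$metrics$f1 %||% NA_real_
  }, 0.0)
  out <- cbind(grid, f1 = f1)
  ok <- !is.na(out$f1)
  cand <- out[ok, ]
  cand <- cand[order(-cand$f1, -cand$window_s, cand$overlap_s), ]
  attr(out, "best") <- list(window_s = cand$window_s[1],
                            overlap_s = cand$overlap_s[1])
  out
}

#' Per-scan performance versus movement count
#'
#' Sorts scans by the number of ultrasound-detected events and reports the
#' Spearman rank correlation of precision and recall with that count (NA
#' when the counts are all tied).
#'
#' @param per_scan A data frame with columns `scan_id`, `precision`,
#'   `recall` (one row per scan).
#' @param tracks Named or ordered list of `fm_track` matching `scan_id`.
#' @return Data frame `(scan_id, n_udfm, precision, recall)` sorted
#'   ascending by `n_udfm`, with attribute `spearman` (named vector).
#' @export
performance_vs_event_count <- function(per_scan, tracks) {
  ids <- vapply(tracks, function(t) t$scan_id, "")
  n_udfm <- vapply(tracks, function(t) nrow(t$events), 0L)
  m <- match(per_scan$scan_id, ids)
  out <- data.frame(scan_id = per_scan$scan_id, n_udfm = n_udfm[m],
                    precision = per_scan$precision, recall = per_scan$recall,
                    stringsAsFactors = FALSE)
  out <- out[order(out$n_udfm), ]
  rownames(out) <- NULL
  sp <- function(v) {
    if (length(unique(out$n_udfm)) < 2L || length(unique(v)) < 2L ||
        anyNA(v)) NA_real_
    else stats::cor(out$n_udfm, v, method = "spearman")
  }
  attr(out, "spearman") <- c(precision = sp(out$precision),
                             recall = sp(out$recall))
  out
}

#' Agreement between maternal perception and ultrasound detection
#'
#' Discretises the session into non-overlapping windows of `window_s`
#' seconds and compares ultrasound-detected-movement windows (reference)
#' with push-button windows (test): `accuracy` is the fraction of windows
#' on which the two agree, `recall` the fraction of ultrasound-positive
#' windows that carry a press, `specificity` the fraction of
#' ultrasound-negative windows without a press. `precision` is event-level:
#' the fraction of ultrasound-detected movements that were signalled by a
#' press, estimated as presses/events (each press signals one movement;
#' capped at 1).
#'
#' @param track An `fm_track` with at least one UDFM event.
#' @param window_s Discretisation window in seconds (default 8).
#' @param duration_s Session length; inferred from the last annotation if
#'   omitted.
#' @return An `fm_metrics` (the `f1` slot is the harmonic mean of the
#'   reported precision and recall), with attribute `counts` (the window
#'   2x2 table) and `n_events`.
#' @export
mpm_vs_udfm_agreement <- function(track, window_s = 8, duration_s = NULL) {
  ev <- track$events
  if (nrow(ev) == 0) stop("track has no UDFM events", call. = FALSE)
  if (is.null(duration_s))
    duration_s <- max(ev$onset_s + ev$duration_s, track$mpm_s, 0)
  if (duration_s <= 0) stop("empty session", call. = FALSE)
  nW <- ceiling(duration_s / window_s)
  starts <- (seq_len(nW) - 1) * window_s
  udfm <- integer(nW); mpm <- integer(nW)
  for (i in seq_len(nrow(ev))) {
    hit <- ev$onset_s[i] < starts + window_s &
      ev$onset_s[i] + ev$duration_s[i] > starts
    udfm[hit] <- 1L
  }
  if (length(track$mpm_s))
    mpm[unique(pmin(floor(track$mpm_s / window_s) + 1, nW))] <- 1L

  cc <- confusion(udfm, mpm)
  precision <- min(1, length(track$mpm_s) / nrow(ev))
  recall <- if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else NA_real_
  specificity <- if (cc$tn + cc$fp > 0) cc$tn / (cc$tn + cc$fp) else NA_real_
  accuracy <- (cc$tp + cc$tn) / nW
  f1 <- if (!is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  out <- structure(list(precision = precision, recall = recall, f1 = f1,
                        specificity = specificity, accuracy = accuracy),
                   class = "fm_metrics")
  attr(out, "counts") <- cc
  attr(out, "n_events") <- nrow(ev)
  out
}
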