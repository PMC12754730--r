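# Confusion-matrix construction, the performance metrics, and the averaging
# schemes used across sensors and scans (movement = positive class).

#' Confusion counts
#'
#' Tallies TP/TN/FP/FN with movement (1) as the positive class.
#' @param y_true,y_pred Equal-length binary 0/1 vectors.
#' @return An object of class `fm_confusion`: list `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  structure(list(tp = sum(y_true == 1L & y_pred == 1L),
                 tn = sum(y_true == 0L & y_pred == 0L),
                 fp = sum(y_true == 0L & y_pred == 1L),
                 fn = sum(y_true == 1L & y_pred == 0L)),
            class = "fm_confusion")
}

as_confusion <- function(tp, tn, fp, fn) {
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn), class = "fm_confusion")
}

#' @export
print.fm_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(true = c("movement", "no movement"),
                              predicted = c("movement", "no movement")))
  print(m)
  invisible(x)
}

#' Performance metrics from confusion counts
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, their harmonic-mean F1,
#' specificity `TN/(TN+FP)` and accuracy. A metric whose denominator is
#' zero is undefined and reported as `NA` with a note; counts may be
#' fractional (averaged matrices).
#'
#' @param counts An `fm_confusion` (or list with `tp`, `tn`, `fp`, `fn`).
#' @param quiet Suppress the note about undefined metrics.
#' @return An object of class `fm_metrics`: `precision`, `recall`, `f1`,
#'   `specificity`, `accuracy` (NA where undefined).
#' @export
metrics <- function(counts, quiet = FALSE) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  specificity <- ratio(tn, tn + fp)
  accuracy <- (tp + tn) / total
  out <- structure(list(precision = precision, recall = recall, f1 = f1,
                        specificity = specificity, accuracy = accuracy),
                   class = "fm_metrics")
  und <- names(out)[vapply(out, is.na, logical(1))]
  if (length(und) && !quiet)
    message("undefined metric(s) due to zero denominator: ",
            paste(und, collapse = ", "))
  out
}

#' @export
print.fm_metrics <- function(x, digits = 3, ...) {
  v <- unlist(x)
  cat(paste(sprintf("%s = %s", names(v), format(round(v, digits))),
            collapse = ", "), "\n")
  invisible(x)
}

mean_counts <- function(counts_list) {
  if (length(counts_list) == 0) stop("empty input", call. = FALSE)
  as_confusion(mean(vapply(counts_list, `[[`, 0, "tp")),
               mean(vapply(counts_list, `[[`, 0, "tn")),
               mean(vapply(counts_list, `[[`, 0, "fp")),
               mean(vapply(counts_list, `[[`, 0, "fn")))
}

#' Aggregate per-sensor confusion matrices (fusion strategy 1)
#'
#' For each scan the six per-sensor TP/TN/FP/FN are averaged element-wise
#' into one per-scan matrix; the per-scan matrices are then averaged
#' element-wise across scans, and the metrics are computed from the final
#' averaged counts.
#'
#' @param per_scan_sensor_counts List over scans, each element a list of
#'   six `fm_confusion` (one per sensor).
#' @param quiet Passed to [metrics()].
#' @return List with `metrics` (`fm_metrics`), the final averaged `counts`,
#'   and `per_scan` counts.
#' @export
aggregate_model1 <- function(per_scan_sensor_counts, quiet = FALSE) {
  if (length(per_scan_sensor_counts) == 0) stop("empty input", call. = FALSE)
  per_scan <- lapply(per_scan_sensor_counts, mean_counts)
  counts <- mean_counts(per_scan)
  list(metrics = metrics(counts, quiet = quiet), counts = counts,
       per_scan = per_scan)
}

#' Aggregate per-scan confusion matrices (fusion strategies 2 and 3)
#'
#' One confusion matrix per scan is averaged element-wise across scans;
#' metrics come from the averaged counts.
#'
#' @param per_scan_counts List of `fm_confusion`, one per scan.
#' @param quiet Passed to [metrics()].
#' @return List with `metrics`, averaged `counts` and `per_scan`.
#' @export
aggregate_model23 <- function(per_scan_counts, quiet = FALSE) {
  if (length(per_scan_counts) == 0) stop("empty input", call. = FALSE)
  counts <- mean_counts(per_scan_counts)
  list(metrics = metrics(counts, quiet = quiet), counts = counts,
       per_scan = per_scan_counts)
}

#' Chronological train/test split of a windowed dataset
#'
#' Windows overlap in time, so a random split would leak test information
#' into training; instead the first `ceiling(fraction * n)` windows (by
#' start time) train and the remainder test. The training size is clamped
#' so at least one window remains on each side.
#'
#' @param dataset An `fm_dataset` with at least 2 windows.
#' @param fraction Training fraction in (0, 1) (default 0.7).
#' @return List with `train` and `test` `fm_dataset`s.
#' @export
split_train_test <- function(dataset, fraction = 0.7) {
  n <- nrow(dataset$X)
  if (n < 2L) stop("need at least 2 windows to split", call. = FALSE)
  if (fraction <= 0 || fraction >= 1)
    stop("'fraction' must lie in (0, 1)", call. = FALSE)
  o <- order(dataset$window_starts_s)
  n_train <- min(max(ceiling(fraction * n), 1L), n - 1L)
  take <- function(i) new_dataset(dataset$X[o[i], , drop = FALSE],
                                  dataset$y[o[i]],
                                  dataset$window_starts_s[o[i]],
                                  dataset$scan_id, dataset$fusion,
                                  dataset$sensor_id)
  list(train = take(seq_len(n_train)), test = take((n_train + 1L):n))
}
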