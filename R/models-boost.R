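# AdaBoost.M1 and RUSBoost on decision-tree weak learners. Both maintain
# weights over the full training set; RUSBoost additionally fits each round's
# learner on a random-undersampled subset so the minority class is not
# swamped, while the weighted error and the weight update always use the
# full set.

boost_guard_eps <- function(n) 1 / (2 * n)

#' AdaBoost.M1 ensemble of decision trees
#'
#' Sample weights start uniform; each round fits a weighted weak learner
#' (a depth-`weak_depth` tree), computes its weighted error `eps_t`, sets
#' the vote weight `alpha_t = learning_rate * 0.5 * log((1 - eps_t)/eps_t)`,
#' multiplies misclassified sample weights up (and correct ones down) and
#' renormalises. Boosting stops early when a round is perfect (`eps_t = 0`:
#' the learner is kept with `eps` floored at `1/(2n)`) or no better than
#' chance (`eps_t >= 0.5`: the round is discarded). The ensemble predicts
#' the sign of `sum(alpha_t * (2 h_t - 1))`, with ties going to class 0.
#'
#' @param x Feature matrix (rows = samples) or an `fm_dataset`.
#' @param y Binary labels (ignored when `x` is an `fm_dataset`); both
#'   classes must be present.
#' @param n_estimators Maximum boosting rounds (default 100).
#' @param weak_depth Depth of each weak-learner tree (default 1: stumps).
#' @param learning_rate Shrinkage on the vote weights (default 1).
#' @param min_samples_leaf Passed to the weak learner.
#' @return An object of class `fm_boost` (`type = "adaboost"`) with
#'   `learners`, `alphas` and per-round errors `eps`.
#' @export
fm_adaboost <- function(x, y = NULL, n_estimators = 100L, weak_depth = 1L,
                        learning_rate = 1.0, min_samples_leaf = 1L) {
  if (inherits(x, "fm_dataset")) { y <- x$y; x <- x$X }
  x <- as.matrix(x); y <- as.integer(y)
  check_two_classes(y)
  n <- length(y)
  w <- rep(1 / n, n)
  learners <- list(); alphas <- numeric(0); epss <- numeric(0)
  for (t in seq_len(n_estimators)) {
    lrn <- fm_tree(x, y, weights = w, max_depth = weak_depth,
                   min_samples_leaf = min_samples_leaf)
    pred <- predict(lrn, x)
    miss <- pred != y
    eps <- sum(w[miss])
    if (eps >= 0.5) break
    eps_eff <- max(eps, boost_guard_eps(n))
    alpha <- learning_rate * 0.5 * log((1 - eps_eff) / eps_eff)
    learners[[length(learners) + 1L]] <- lrn
    alphas <- c(alphas, alpha)
    epss <- c(epss, eps)
    if (eps <= 0) break
    w <- w * exp(ifelse(miss, alpha, -alpha))
    w <- w / sum(w)
  }
  if (length(learners) == 0L)
    stop("no weak learner better than chance; boosting failed", call. = FALSE)
  new_boost(learners, alphas, epss, ncol(x), "adaboost")
}

check_two_classes <- function(y) {
  if (length(unique(y)) < 2L)
    stop("both classes must be present in the training labels", call. = FALSE)
  if (!all(y %in% c(0L, 1L)))
    stop("labels must be binary 0/1", call. = FALSE)
  invisible(y)
}

new_boost <- function(learners, alphas, epss, n_features, type) {
  structure(list(learners = learners, alphas = alphas, eps = epss,
                 n_features = n_features, type = type, classes = c(0L, 1L)),
            class = "fm_boost")
}

#' Random undersampling of the majority class
#'
#' Returns all minority-class indices plus a uniform random subset of the
#' majority class of size `round(ratio * n_minority)` (all of it, if the
#' majority is already at or below that size). Deterministic given `seed`.
#'
#' @param y Binary 0/1 labels with both classes present.
#' @param ratio Majority:minority ratio after sampling (default 1 = 50:50).
#' @param seed Integer seed.
#' @return Sorted integer index vector into `y`.
#' @export
rus_sample <- function(y, ratio = 1.0, seed = 1L) {
  y <- as.integer(y)
  check_two_classes(y)
  n1 <- sum(y == 1L); n0 <- length(y) - n1
  minority <- if (n1 <= n0) 1L else 0L
  min_idx <- which(y == minority)
  maj_idx <- which(y != minority)
  target <- round(ratio * length(min_idx))
  if (length(maj_idx) > target)
    maj_idx <- with_seed(seed, sample(maj_idx, target))
  sort(c(min_idx, maj_idx))
}

#' RUSBoost: boosting with per-round random undersampling
#'
#' Follows the AdaBoost.M1 scheme of [fm_adaboost()] except that each round
#' draws a random-undersampled subset (via [rus_sample()] on a
#' round-specific substream of `seed`), fits the weak learner on that
#' subset using the current full-set weights restricted to it, then
#' evaluates the weighted error and updates the weights on the full
#' training set. Rounds no better than chance are discarded and resampled
#' (up to 10 consecutive attempts).
#'
#' @inheritParams fm_adaboost
#' @param ratio Majority:minority ratio after undersampling (default 1).
#' @param seed Integer seed driving the per-round subsamples.
#' @return An object of class `fm_boost` (`type = "rusboost"`).
#' @export
fm_rusboost <- function(x, y = NULL, n_estimators = 100L, weak_depth = 1L,
                        learning_rate = 1.0, ratio = 1.0, seed = 1L,
                        min_samples_leaf = 1L) {
  if (inherits(x, "fm_dataset")) { y <- x$y; x <- x$X }
  x <- as.matrix(x); y <- as.integer(y)
  check_two_classes(y)
  n <- length(y)
  w <- rep(1 / n, n)
  learners <- list(); alphas <- numeric(0); epss <- numeric(0)
  t <- 0L; attempts <- 0L
  while (length(learners) < n_estimators) {
    t <- t + 1L
    idx <- rus_sample(y, ratio, substream(seed, t))
    ws <- w[idx] / sum(w[idx])
    lrn <- fm_tree(x[idx, , drop = FALSE], y[idx], weights = ws,
                   max_depth = weak_depth, min_samples_leaf = min_samples_leaf)
    pred <- predict(lrn, x)
    miss <- pred != y
    eps <- sum(w[miss])
    if (eps >= 0.5) {
      attempts <- attempts + 1L
      if (attempts >= 10L) break
      next
    }
    attempts <- 0L
    eps_eff <- max(eps, boost_guard_eps(n))
    alpha <- learning_rate * 0.5 * log((1 - eps_eff) / eps_eff)
    learners[[length(learners) + 1L]] <- lrn
    alphas <- c(alphas, alpha)
    epss <- c(epss, eps)
    if (eps <= 0) break
    w <- w * exp(ifelse(miss, alpha, -alpha))
    w <- w / sum(w)
  }
  if (length(learners) == 0L)
    stop("no weak learner better than chance; boosting failed", call. = FALSE)
  new_boost(learners, alphas, epss, ncol(x), "rusboost")
}

#' Weighted-vote score of a boosted ensemble
#'
#' `sum_t alpha_t * (2 h_t(x) - 1)`: positive means class 1.
#' @param model An `fm_boost`.
#' @param X Feature matrix.
#' @return Numeric score per row of `X`.
#' @export
boost_score <- function(model, X) {
  if (inherits(X, "fm_dataset")) X <- X$X
  X <- as.matrix(X)
  score <- numeric(nrow(X))
  for (t in seq_along(model$learners))
    score <- score + model$alphas[t] * (2 * predict(model$learners[[t]], X) - 1)
  score
}

#' @param object An `fm_boost`.
#' @param newdata Feature matrix or `fm_dataset`.
#' @param type `"class"` for 0/1 labels, `"score"` for the raw vote sum.
#' @param ... Unused.
#' @rdname fm_adaboost
#' @export
predict.fm_boost <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "fm_dataset")) newdata <- newdata$X
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("feature dimension mismatch", call. = FALSE)
  s <- boost_score(object, newdata)
  if (type == "score") s else as.integer(s > 0)  # tie (0) -> class 0
}

#' @export
print.fm_boost <- function(x, ...) {
  cat(if (x$type == "rusboost") "RUSBoost" else "AdaBoost.M1", "ensemble:",
      length(x$learners), "weak learners, final round error",
      format(tail(x$eps, 1), digits = 3), "\n")
  invisible(x)
}

#' @export
summary.fm_boost <- function(object, ...) {
  cat("Ensemble type:", object$type, "\n")
  cat("Rounds kept:", length(object$learners), "\n")
  cat("Training-error bound (prod 2*sqrt(eps(1-eps))):",
      format(prod(2 * sqrt(object$eps * (1 - object$eps))), digits = 4), "\n")
  invisible(object)
}
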