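# k-nearest-neighbour classifier (lazy learner: fit stores the training set).

#' k-nearest-neighbour classifier
#'
#' Stores the training data; prediction takes a majority vote among the `k`
#' nearest training points under the chosen distance metric. An odd `k`
#' avoids two-class ties; any remaining tie (even `k`, or weighted votes)
#' is broken toward class 0 (non-movement).
#'
#' @param x Numeric feature matrix (rows = samples) or an `fm_dataset`.
#' @param y Binary labels (ignored when `x` is an `fm_dataset`).
#' @param k Number of neighbours (default 3, odd).
#' @param metric One of `"euclidean"`, `"manhattan"`, `"chebyshev"`,
#'   `"minkowski"`.
#' @param p Minkowski exponent (used only for `metric = "minkowski"`).
#' @param weighting `"uniform"` votes or `"inverse"` distance weighting
#'   (an exact-match neighbour outvotes all others).
#' @return An object of class `fm_knn`.
#' @export
fm_knn <- function(x, y = NULL, k = 3L,
                   metric = c("euclidean", "manhattan", "chebyshev", "minkowski"),
                   p = 3, weighting = c("uniform", "inverse")) {
  if (inherits(x, "fm_dataset")) { y <- x$y; x <- x$X }
  x <- as.matrix(x)
  metric <- match.arg(metric)
  weighting <- match.arg(weighting)
  if (k < 1 || k > nrow(x))
    stop("'k' must lie in [1, n_train]", call. = FALSE)
  structure(list(x = x, y = as.integer(y), k = as.integer(k),
                 metric = metric, p = p, weighting = weighting),
            class = "fm_knn")
}

#' @export
print.fm_knn <- function(x, ...) {
  cat("kNN classifier: k =", x$k, ", metric =", x$metric,
      ", n_train =", nrow(x$x), "\n")
  invisible(x)
}

knn_distances <- function(train, query, metric, p) {
  # one query row against all training rows
  d <- sweep(train, 2, query)
  switch(metric,
         euclidean = sqrt(rowSums(d^2)),
         manhattan = rowSums(abs(d)),
         chebyshev = apply(abs(d), 1, max),
         minkowski = rowSums(abs(d)^p)^(1 / p))
}

#' @param object An `fm_knn` model.
#' @param newdata Feature matrix (or `fm_dataset`) to classify.
#' @param ... Unused.
#' @return Integer 0/1 predictions.
#' @rdname fm_knn
#' @export
predict.fm_knn <- function(object, newdata, ...) {
  if (inherits(newdata, "fm_dataset")) newdata <- newdata$X
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$x))
    stop("feature dimension mismatch", call. = FALSE)
  apply(newdata, 1, function(q) {
    d <- knn_distances(object$x, q, object$metric, object$p)
    nn <- order(d)[seq_len(object$k)]
    w <- if (object$weighting == "uniform") rep(1, object$k) else {
      dd <- d[nn]
      if (any(dd == 0)) as.numeric(dd == 0) else 1 / dd
    }
    v1 <- sum(w[object$y[nn] == 1L])
    v0 <- sum(w) - v1
    as.integer(v1 > v0)  # tie -> class 0
  })
}
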