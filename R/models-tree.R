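# Weighted binary decision tree with axis-aligned threshold splits chosen by
# exhaustive search over midpoints of sorted unique feature values. Supports
# per-sample weights (required by the boosting wrappers).

node_impurity <- function(w1, w0, criterion) {
  w <- w1 + w0
  p1 <- ifelse(w > 0, w1 / w, 0)
  p0 <- 1 - p1
  if (criterion == "gini") 1 - p1^2 - p0^2
  else {
    h <- function(p) ifelse(p > 0, -p * log2(p), 0)
    h(p1) + h(p0)
  }
}

# Best split of one feature: cumulative weighted class sums along the sort
# order; candidates are boundaries between distinct consecutive values.
best_split_feature <- function(x, y, w, criterion, min_leaf) {
  o <- order(x)
  xs <- x[o]; ys <- y[o]; ws <- w[o]
  n <- length(xs)
  c1 <- cumsum(ws * (ys == 1L)); c0 <- cumsum(ws * (ys == 0L))
  W1 <- c1[n]; W0 <- c0[n]; W <- W1 + W0
  i <- seq_len(n - 1L)
  valid <- xs[i] < xs[i + 1L] & i >= min_leaf & (n - i) >= min_leaf
  if (!any(valid)) return(NULL)
  i <- i[valid]
  wl <- c1[i] + c0[i]
  imp <- (wl * node_impurity(c1[i], c0[i], criterion) +
          (W - wl) * node_impurity(W1 - c1[i], W0 - c0[i], criterion)) / W
  b <- which.min(imp)
  list(threshold = (xs[i[b]] + xs[i[b] + 1L]) / 2, impurity = imp[b])
}

leaf_node <- function(y, w) {
  w1 <- sum(w[y == 1L])
  list(type = "leaf", class = as.integer(w1 > sum(w) - w1))  # tie -> 0
}

grow_tree <- function(X, y, w, depth, criterion, min_leaf) {
  if (depth == 0L || length(unique(y)) < 2L || length(y) < 2L * min_leaf)
    return(leaf_node(y, w))
  best <- NULL
  for (j in seq_len(ncol(X))) {
    s <- best_split_feature(X[, j], y, w, criterion, min_leaf)
    if (!is.null(s) && (is.null(best) || s$impurity < best$impurity - 1e-15))
      best <- c(s, feature = j)
  }
  if (is.null(best)) return(leaf_node(y, w))
  left <- X[, best$feature] <= best$threshold
  list(type = "node", feature = best$feature, threshold = best$threshold,
       left = grow_tree(X[left, , drop = FALSE], y[left], w[left],
                        depth - 1L, criterion, min_leaf),
       right = grow_tree(X[!left, , drop = FALSE], y[!left], w[!left],
                         depth - 1L, criterion, min_leaf))
}

#' Decision-tree classifier with weighted Gini splits
#'
#' Grows a binary tree top-down: each node tries every feature and every
#' boundary between distinct sorted values, keeping the split with the
#' lowest weighted impurity (Gini index by default). Leaves predict the
#' weighted majority class (ties toward class 0). Per-sample weights make
#' the tree usable as a boosting weak learner.
#'
#' @param x Feature matrix (rows = samples) or an `fm_dataset`.
#' @param y Binary labels (ignored when `x` is an `fm_dataset`).
#' @param weights Optional non-negative per-sample weights (default uniform).
#' @param max_depth Maximum number of split layers (default 3; 1 gives a
#'   decision stump).
#' @param criterion `"gini"` or `"entropy"` impurity.
#' @param min_samples_leaf Minimum samples on each side of a split.
#' @return An object of class `fm_tree`.
#' @export
fm_tree <- function(x, y = NULL, weights = NULL, max_depth = 3L,
                    criterion = c("gini", "entropy"), min_samples_leaf = 1L) {
  if (inherits(x, "fm_dataset")) { y <- x$y; x <- x$X }
  x <- as.matrix(x)
  y <- as.integer(y)
  criterion <- match.arg(criterion)
  if (max_depth < 1L) stop("'max_depth' must be >= 1", call. = FALSE)
  if (length(y) < 1L) stop("need at least one sample", call. = FALSE)
  if (is.null(weights)) weights <- rep(1 / length(y), length(y))
  stopifnot(length(weights) == length(y), all(weights >= 0))
  structure(list(root = grow_tree(x, y, weights, as.integer(max_depth),
                                  criterion, as.integer(min_samples_leaf)),
                 n_features = ncol(x), max_depth = max_depth,
                 criterion = criterion),
            class = "fm_tree")
}

tree_depth <- function(node) {
  if (node$type == "leaf") 0L
  else 1L + max(tree_depth(node$left), tree_depth(node$right))
}

#' @export
print.fm_tree <- function(x, ...) {
  cat("Decision tree (", x$criterion, "): depth ", tree_depth(x$root),
      " of max ", x$max_depth, ", ", x$n_features, " features\n", sep = "")
  invisible(x)
}

predict_node <- function(node, X, idx, out) {
  if (node$type == "leaf") { out[idx] <- node$class; return(out) }
  left <- X[idx, node$feature] <= node$threshold
  out <- predict_node(node$left, X, idx[left], out)
  predict_node(node$right, X, idx[!left], out)
}

#' @param object An `fm_tree`.
#' @param newdata Feature matrix or `fm_dataset`.
#' @param ... Unused.
#' @rdname fm_tree
#' @export
predict.fm_tree <- function(object, newdata, ...) {
  if (inherits(newdata, "fm_dataset")) newdata <- newdata$X
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("feature dimension mismatch", call. = FALSE)
  predict_node(object$root, newdata, seq_len(nrow(newdata)),
               integer(nrow(newdata)))
}
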