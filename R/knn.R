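#' Cosine distance between two vectors
#'
#' `1 - (u . v) / (||u|| ||v||)`: zero for identical directions, 1 for
#' orthogonal vectors, up to 2 for opposite directions. Undefined (an
#' error) for zero-norm vectors.
#'
#' @param u,v Numeric vectors of equal length with positive norm.
#' @return Distance in \[0, 2\].
#' @examples
#' cosine_distance(c(1, 0), c(0, 1))  # 1
#' cosine_distance(c(1, 1), c(1, 0))  # 1 - 1/sqrt(2)
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v)) stop("dimension mismatch", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("cosine distance undefined for zero-norm vectors", call. = FALSE)
  }
  1 - sum(u * v) / (nu * nv)
}

#' Fit a cosine-distance k-nearest-neighbour classifier
#'
#' Stores the training patterns shifted by a fixed positive per-coordinate
#' offset. The classifier expects standardized features, where a point can
#' fall arbitrarily close to the origin (the feature means) and make cosine
#' distance ill-defined; the offset moves all vectors into the positive
#' orthant, safely beyond the z-score range of the data, so directions stay
#' meaningful and norms stay positive.
#'
#' @param x Feature matrix (standardized features expected) or
#'   `ploidy_dataset`.
#' @param y Labels (ignored when `x` is a dataset).
#' @param k Neighbour count, between 1 and the number of training rows.
#' @param offset Positive per-coordinate shift applied to stored patterns
#'   and queries (default 3).
#' @return Object of class `knn_model`.
#' @export
knn_fit <- function(x, y = NULL, k = 5, offset = 3) {
  if (inherits(x, "ploidy_dataset")) { y <- x$labels; x <- x$features }
  x <- as_feature_matrix(x)
  y <- droplevels(factor(y))
  check_number(k, "k", lower = 1)
  check_number(offset, "offset")
  k <- as.integer(k)
  if (nrow(x) == 0) stop("empty training set", call. = FALSE)
  if (k > nrow(x)) stop("k exceeds the number of training patterns",
                        call. = FALSE)
  structure(
    list(patterns = x + offset, labels = y, classes = levels(y),
         k = k, offset = offset),
    class = "knn_model"
  )
}

#' @export
print.knn_model <- function(x, ...) {
  cat("<knn_model> ", nrow(x$patterns), " patterns, k = ", x$k,
      ", offset = ", format(x$offset), "\n", sep = "")
  invisible(x)
}

knn_vote <- function(m, q) {
  if (sqrt(sum(q^2)) == 0) {
    stop("zero-norm query after offset; cosine distance undefined",
         call. = FALSE)
  }
  d <- vapply(seq_len(nrow(m$patterns)),
              function(i) cosine_distance(q, m$patterns[i, ]), numeric(1))
  ord <- order(d)                       # stable: ties keep training order
  nn <- ord[seq_len(m$k)]
  tab <- table(factor(as.character(m$labels[nn]), levels = m$classes))
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1) {
    # vote tie: class of the single nearest neighbour; if that class is not
    # among the tied ones, fall back to the earliest tied class in order
    nearest <- as.character(m$labels[ord[1]])
    if (nearest %in% top) top <- nearest else top <- top[1]
  }
  top[1]
}

#' @export
#' @param object A `knn_model`.
#' @param x Query feature matrix on the training (standardized) scale; the
#'   model's offset is added internally.
#' @param ... Unused.
#' @return Factor of predicted labels. Distance ties at the k-th rank are
#'   resolved by stable training-set order; vote ties by the class of the
#'   single nearest neighbour.
#' @rdname knn_fit
predict.knn_model <- function(object, x, ...) {
  x <- as_feature_matrix(x) + object$offset
  pred <- vapply(seq_len(nrow(x)),
                 function(i) knn_vote(object, x[i, ]), character(1))
  factor(pred, levels = object$classes)
}

#' Select k by leave-one-out accuracy
#'
#' Scores each candidate neighbour count by leave-one-out classification of
#' the training set under the same cosine-distance rule and returns the
#' accuracy maximizer; ties go to the smaller k.
#'
#' @param x Feature matrix or `ploidy_dataset`.
#' @param y Labels (ignored when `x` is a dataset).
#' @param candidates Candidate k values, each in \[1, n - 1\] (default
#'   1, 3, 5, 7, 9).
#' @param offset Positive per-coordinate shift, as in [knn_fit()].
#' @return List with `k`, `accuracy`, and `grid_accuracy`.
#' @export
select_k <- function(x, y = NULL, candidates = c(1, 3, 5, 7, 9), offset = 3) {
  if (inherits(x, "ploidy_dataset")) { y <- x$labels; x <- x$features }
  x <- as_feature_matrix(x)
  y <- droplevels(factor(y))
  if (length(candidates) == 0) stop("empty candidate set", call. = FALSE)
  n <- nrow(x)
  if (any(candidates < 1 | candidates > n - 1)) {
    stop("candidates must lie in [1, n_train - 1]", call. = FALSE)
  }
  acc <- vapply(candidates, function(k) {
    correct <- vapply(seq_len(n), function(i) {
      m <- knn_fit(x[-i, , drop = FALSE], y[-i], k = k, offset = offset)
      as.character(predict(m, x[i, , drop = FALSE])) == as.character(y[i])
    }, logical(1))
    mean(correct)
  }, numeric(1))
  names(acc) <- candidates
  best <- max(acc)
  k <- min(candidates[acc == best])     # ties -> smaller k
  list(k = k, accuracy = best, grid_accuracy = acc)
}
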