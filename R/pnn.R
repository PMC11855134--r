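#' Gaussian pattern-layer kernel
#'
#' Activation of one pattern unit: `exp(-||x - xi||^2 / (2 sigma^2))`, the
#' Parzen kernel on the squared Euclidean distance between a query and a
#' stored training pattern.
#'
#' @param x,xi Numeric feature vectors of equal length.
#' @param sigma Smoothing parameter, > 0.
#' @return Activation in (0, 1].
#' @examples
#' pnn_kernel(c(0, 0), c(1, 0), 1)  # exp(-0.5)
#' @export
pnn_kernel <- function(x, xi, sigma) {
  check_number(sigma, "sigma")
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (length(x) != length(xi)) stop("dimension mismatch", call. = FALSE)
  exp(-sum((x - xi)^2) / (2 * sigma^2))
}

#' Fit a probabilistic neural network
#'
#' A PNN stores every training pattern (pattern layer). At prediction, the
#' summation layer adds the Gaussian kernel activations per class,
#' S_j = sum over class-j patterns of exp(-||x - xi||^2 / (2 sigma^2)),
#' and the output layer normalizes to class posteriors
#' P(C_j | x) = S_j / sum_k S_k. With the balanced training sets used here,
#' the unweighted kernel sums give the same argmax as the 1/N_j-weighted
#' classic formulation.
#'
#' @param x Numeric feature matrix (standardized features expected) or a
#'   `ploidy_dataset`.
#' @param y Factor/character labels (ignored when `x` is a dataset).
#' @param sigma Smoothing parameter, > 0.
#' @return Object of class `pnn_model`.
#' @export
pnn_fit <- function(x, y = NULL, sigma = 0.2) {
  if (inherits(x, "ploidy_dataset")) { y <- x$labels; x <- x$features }
  x <- as_feature_matrix(x)
  y <- droplevels(factor(y))
  check_number(sigma, "sigma")
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (nrow(x) == 0) stop("empty training set", call. = FALSE)
  cnt <- table(y)
  if (any(cnt == 0) || nlevels(y) < 2) {
    stop("every class must have at least one training pattern", call. = FALSE)
  }
  structure(
    list(patterns = x, labels = y, classes = levels(y),
         class_counts = as.integer(cnt), sigma = sigma),
    class = "pnn_model"
  )
}

#' @export
print.pnn_model <- function(x, ...) {
  cat("<pnn_model> ", nrow(x$patterns), " patterns, ",
      length(x$classes), " classes, sigma = ", format(x$sigma), "\n", sep = "")
  invisible(x)
}

#' PNN class posteriors
#'
#' @param m A `pnn_model`.
#' @param x Query feature matrix (rows = queries) or single vector, on the
#'   same (standardized) scale as the training patterns.
#' @return Matrix of posteriors, one row per query, one column per class;
#'   rows sum to 1. Kernel sums are rescaled by the per-row nearest-pattern
#'   activation before normalization, which cancels in the ratio and keeps
#'   posteriors finite for arbitrarily small `sigma`.
#' @export
pnn_posterior <- function(m, x) {
  stopifnot(inherits(m, "pnn_model"))
  x <- as_feature_matrix(x)
  d2 <- cross_dist2(x, m$patterns)
  # subtract per-row min distance: multiplies each row's kernels by a common
  # factor, which the output-layer normalization cancels
  d2 <- d2 - apply(d2, 1, min)
  act <- exp(-d2 / (2 * m$sigma^2))
  ind <- outer(as.character(m$labels), m$classes, "==") * 1
  s <- act %*% ind
  colnames(s) <- m$classes
  s / rowSums(s)
}

#' @export
#' @rdname pnn_posterior
#' @param object A `pnn_model`.
#' @param ... Unused.
#' @return For `predict`: factor of predicted class labels; ties go to the
#'   earliest class in the model's fixed class ordering.
predict.pnn_model <- function(object, x, ...) {
  post <- pnn_posterior(object, x)
  factor(object$classes[apply(post, 1, which.max)], levels = object$classes)
}

#' Select the PNN smoothing parameter by leave-one-out accuracy
#'
#' Evaluates every candidate sigma by leave-one-out classification of the
#' training set (each pattern scored against all others) and returns the
#' accuracy maximizer; ties are broken toward the largest sigma (the
#' smoothest model).
#'
#' @param x Feature matrix or `ploidy_dataset`.
#' @param y Labels (ignored when `x` is a dataset).
#' @param grid Positive candidate sigma values.
#' @return List with `sigma` (the selected value), `accuracy` (its
#'   leave-one-out accuracy) and `grid_accuracy` (named vector over the
#'   grid).
#' @export
select_sigma <- function(x, y = NULL,
                         grid = c(0.25, 0.35, 0.5, 0.75, 1, 1.5, 2)) {
  if (inherits(x, "ploidy_dataset")) { y <- x$labels; x <- x$features }
  x <- as_feature_matrix(x)
  y <- droplevels(factor(y))
  if (length(grid) == 0) stop("empty sigma grid", call. = FALSE)
  if (any(grid <= 0)) stop("sigma candidates must be > 0", call. = FALSE)
  n <- nrow(x)
  d2 <- cross_dist2(x, x)
  diag(d2) <- Inf                       # exclude self-activation
  shift <- apply(d2, 1, min)
  ind <- outer(as.character(y), levels(y), "==") * 1
  acc <- vapply(grid, function(s) {
    act <- exp(-(d2 - shift) / (2 * s^2))
    act[!is.finite(act)] <- 0
    sums <- act %*% ind
    pred <- levels(y)[apply(sums, 1, which.max)]
    mean(pred == as.character(y))
  }, numeric(1))
  names(acc) <- format(grid)
  best <- max(acc)
  sigma <- max(grid[acc == best])       # ties -> larger sigma
  list(sigma = sigma, accuracy = best, grid_accuracy = acc)
}
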