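#' PCA-based outlier screen
#'
#' Removes multivariate outliers in principal-component space: features are
#' standardized, projected onto principal components, and each row's
#' Hotelling-style squared Mahalanobis distance (sum of squared standardized
#' PC scores) is compared against the chi-square quantile at 1 - alpha with
#' as many degrees of freedom as features.
#'
#' @param d A [ploidy_dataset()] with at least 3 rows.
#' @param alpha Significance level of the screen (default 0.025); smaller
#'   alpha removes fewer points.
#' @return List with `dataset` (survivors, a `ploidy_dataset`) and `removed`
#'   (integer indices of removed rows in the input ordering).
#' @export
pca_outlier_filter <- function(d, alpha = 0.025) {
  stopifnot(inherits(d, "ploidy_dataset"))
  check_number(alpha, "alpha", lower = 0, upper = 1)
  x <- d$features
  if (nrow(x) < 3) stop("need at least 3 rows to screen outliers",
                        call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds < 1e-12)) {
    stop("degenerate covariance: feature(s) with zero variance: ",
         paste(colnames(x)[sds < 1e-12], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  keep_pc <- pc$sdev > 1e-10
  if (!any(keep_pc)) stop("degenerate covariance in PC space", call. = FALSE)
  z <- sweep(pc$x[, keep_pc, drop = FALSE], 2, pc$sdev[keep_pc], "/")
  t2 <- rowSums(z^2)
  cutoff <- stats::qchisq(1 - alpha, df = ncol(x))
  removed <- which(t2 > cutoff)
  keep <- setdiff(seq_len(nrow(x)), removed)
  list(dataset = subset_dataset(d, keep), removed = removed)
}

#' Fit a feature standardizer
#'
#' Records per-feature mean and standard deviation of the training features
#' so test data can be transformed with training statistics only.
#'
#' @param d A `ploidy_dataset` or numeric feature matrix.
#' @return An object of class `standardizer` with `mean` and `sd` vectors
#'   (original units).
#' @export
fit_standardizer <- function(d) {
  x <- if (inherits(d, "ploidy_dataset")) d$features else as_feature_matrix(d)
  if (nrow(x) == 0) stop("cannot standardize an empty dataset", call. = FALSE)
  mu <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  if (anyNA(sds) || any(sds < 1e-12)) {
    stop("zero-variance feature; standardization undefined", call. = FALSE)
  }
  structure(list(mean = mu, sd = sds), class = "standardizer")
}

#' Apply / invert a standardizer
#'
#' @param s A `standardizer` from [fit_standardizer()].
#' @param x Numeric feature matrix (or `ploidy_dataset`) in original units.
#' @return Matrix of z-scored features.
#' @export
apply_standardizer <- function(s, x) {
  stopifnot(inherits(s, "standardizer"))
  x <- if (inherits(x, "ploidy_dataset")) x$features else as_feature_matrix(x)
  sweep(sweep(x, 2, s$mean), 2, s$sd, "/")
}

#' @rdname apply_standardizer
#' @param z Matrix of z-scored features.
#' @export
invert_standardizer <- function(s, z) {
  stopifnot(inherits(s, "standardizer"))
  sweep(sweep(as_feature_matrix(z), 2, s$sd, "*"), 2, s$mean, "+")
}

#' Stratified train/test split
#'
#' Draws `train_per_class` rows per ploidy class into the training set (a
#' seeded per-class shuffle) and leaves the remainder as the test set. The
#' default of 19 per class partitions the default 72-row balanced dataset
#' into 57 training and 15 testing instances, so accuracies are exact
#' multiples of 1/57 and 1/15.
#'
#' @param d A balanced [ploidy_dataset()].
#' @param train_per_class Training rows per class (default 19).
#' @param seed Integer seed.
#' @return Object of class `split_dataset`: list with `train`, `test`
#'   (`ploidy_dataset`s), `train_idx`, `test_idx` (row indices into `d`),
#'   and `seed`.
#' @export
stratified_split <- function(d, train_per_class = 19, seed = 1L) {
  stopifnot(inherits(d, "ploidy_dataset"))
  check_seed(seed)
  check_number(train_per_class, "train_per_class", lower = 0)
  train_per_class <- as.integer(train_per_class)
  cc <- class_counts(d)
  deficient <- names(cc)[cc < train_per_class]
  if (length(deficient) > 0) {
    stop("class(es) with fewer than train_per_class rows: ",
         paste(deficient, collapse = ", "), call. = FALSE)
  }
  train_idx <- with_seed(seed, {
    unlist(lapply(PLOIDY_CLASSES, function(cl) {
      rows <- which(d$labels == cl)
      sort(sample(rows, train_per_class))
    }), use.names = FALSE)
  })
  test_idx <- setdiff(seq_len(n_instances(d)), train_idx)
  structure(
    list(train = subset_dataset(d, train_idx),
         test = subset_dataset(d, test_idx),
         train_idx = train_idx, test_idx = test_idx, seed = as.integer(seed)),
    class = "split_dataset"
  )
}

#' @export
print.split_dataset <- function(x, ...) {
  cat("<split_dataset> train n =", n_instances(x$train),
      "/ test n =", n_instances(x$test), "\n")
  invisible(x)
}

#' Write a split manifest as JSON
#'
#' Records per-class train/test row indices, the split seed and the
#' standardization parameters, so a partition can be reconstructed exactly.
#'
#' @param split A `split_dataset` from [stratified_split()].
#' @param standardizer A `standardizer` fitted on the training set.
#' @param path Output path for the JSON manifest.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(split, standardizer, path) {
  stopifnot(inherits(split, "split_dataset"),
            inherits(standardizer, "standardizer"))
  by_class <- function(d, idx) {
    stats::setNames(lapply(PLOIDY_CLASSES, function(cl) {
      idx[as.character(d$labels) == cl]
    }), PLOIDY_CLASSES)
  }
  manifest <- list(
    seed = split$seed,
    train_indices = by_class(split$train, split$train_idx),
    test_indices = by_class(split$test, split$test_idx),
    standardization = list(mean = as.list(standardizer$mean),
                           sd = as.list(standardizer$sd))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
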