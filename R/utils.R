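#' @keywords internal
"_PACKAGE"

# Canonical class ordering used everywhere: tie-breaks, confusion-matrix axes,
# posterior columns.
PLOIDY_CLASSES <- c("diploid", "mixoploid", "tetraploid")

#' Canonical ploidy class labels
#'
#' Returns the fixed class ordering (diploid, mixoploid, tetraploid) used for
#' tie-breaking, posterior columns and confusion-matrix axes throughout the
#' package.
#'
#' @return Character vector of the three class labels, in canonical order.
#' @export
ploidy_classes <- function() PLOIDY_CLASSES

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so no function leaks global random state.
with_seed <- function(seed, expr) {
  check_seed(seed)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

check_seed <- function(seed) {
  if (length(seed) != 1L || !is.numeric(seed) || is.na(seed) ||
      seed != round(seed)) {
    stop("`seed` must be a single integer value", call. = FALSE)
  }
  invisible(as.integer(seed))
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("`%s` must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  }
  invisible(x)
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  storage.mode(x) <- "double"
  x
}

# Squared Euclidean cross-distance matrix between rows of a (m x d) and
# b (n x d); clamped at zero to absorb floating-point negatives.
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}
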