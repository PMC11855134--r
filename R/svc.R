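# Soft-margin RBF support-vector classifier, one-vs-one multiclass.
#
# Each binary subproblem maximizes the standard dual
#   sum(a) - 1/2 sum_ij a_i a_j y_i y_j K(x_i, x_j),  0 <= a_i <= C,
#   sum(a_i y_i) = 0
# with K(xi, x) = exp(-gamma ||x - xi||^2), solved by sequential minimal
# optimization with a deterministic second-choice heuristic (maximal
# |E_i - E_j|), so fits are reproducible without any random state.

smo_solve <- function(K, y, C, tol = 1e-3, max_passes = 200,
                      max_iter = 100000L) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  fcache <- function() drop(K %*% (alpha * y)) + b
  passes <- 0L
  iter <- 0L
  while (passes < max_passes) {
    changed <- 0L
    f <- fcache()
    E <- f - y
    for (i in seq_len(n)) {
      iter <- iter + 1L
      if (iter > max_iter) {
        stop("SMO failed to converge within the iteration cap", call. = FALSE)
      }
      ri <- E[i] * y[i]
      if ((ri < -tol && alpha[i] < C) || (ri > tol && alpha[i] > 0)) {
        # try partners in order of decreasing |E_i - E_j| until one yields
        # progress; skipping a blocked partner must not strand the violator
        for (j in order(-abs(E - E[i]))) {
          if (j == i) next
          ai_old <- alpha[i]; aj_old <- alpha[j]
          if (y[i] != y[j]) {
            L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
          } else {
            L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
          }
          if (H - L < 1e-12) next
          eta <- 2 * K[i, j] - K[i, i] - K[j, j]
          if (eta >= -1e-12) next
          aj <- aj_old - y[j] * (E[i] - E[j]) / eta
          aj <- min(H, max(L, aj))
          if (abs(aj - aj_old) < 1e-7) next
          ai <- ai_old + y[i] * y[j] * (aj_old - aj)
          b1 <- b - E[i] - y[i] * (ai - ai_old) * K[i, i] -
            y[j] * (aj - aj_old) * K[i, j]
          b2 <- b - E[j] - y[i] * (ai - ai_old) * K[i, j] -
            y[j] * (aj - aj_old) * K[j, j]
          b <- if (ai > 0 && ai < C) b1
               else if (aj > 0 && aj < C) b2
               else (b1 + b2) / 2
          alpha[i] <- ai; alpha[j] <- aj
          f <- fcache()
          E <- f - y
          changed <- changed + 1L
          break
        }
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
    if (changed == 0L && passes >= 1L) break
  }
  list(alpha = alpha, b = b)
}

rbf_kernel_matrix <- function(a, b, gamma) exp(-gamma * cross_dist2(a, b))

#' Fit an RBF support-vector classifier
#'
#' One-vs-one decomposition over the class pairs, each binary soft-margin
#' subproblem solved in the dual by SMO; prediction takes the decision sign
#' `f(x) = sign(sum_i a_i y_i K(x_i, x) + b)` of each subproblem and a
#' majority vote across subproblems.
#'
#' @param x Feature matrix (standardized features expected) or
#'   `ploidy_dataset`.
#' @param y Labels (ignored when `x` is a dataset).
#' @param C Box constraint, > 0 (default 1).
#' @param gamma RBF kernel width, > 0; default `1 / (2 * mean per-feature
#'   variance)` of the training features.
#' @param tol KKT tolerance of the SMO solver (default 1e-3).
#' @return Object of class `svc_model` holding, per subproblem, the support
#'   vectors, dual coefficients, signed labels and bias.
#' @export
svc_fit <- function(x, y = NULL, C = 1, gamma = NULL, tol = 1e-3) {
  if (inherits(x, "ploidy_dataset")) { y <- x$labels; x <- x$features }
  x <- as_feature_matrix(x)
  y <- droplevels(factor(y))
  check_number(C, "C", lower = 1e-12)
  if (nlevels(y) < 2) stop("need at least 2 classes", call. = FALSE)
  if (is.null(gamma)) gamma <- 1 / (2 * mean(apply(x, 2, stats::var)))
  check_number(gamma, "gamma", lower = 1e-12)
  cls <- levels(y)
  pairs <- utils::combn(cls, 2, simplify = FALSE)
  subproblems <- lapply(pairs, function(pr) {
    sel <- y %in% pr
    xs <- x[sel, , drop = FALSE]
    ys <- ifelse(y[sel] == pr[1], 1, -1)   # +1 = earlier class in order
    K <- rbf_kernel_matrix(xs, xs, gamma)
    sol <- tryCatch(
      smo_solve(K, ys, C, tol = tol),
      error = function(e) {
        stop(sprintf("subproblem %s vs %s: %s", pr[1], pr[2],
                     conditionMessage(e)), call. = FALSE)
      }
    )
    sv <- sol$alpha > 1e-8
    list(classes = pr, x = xs, y = ys, alpha = sol$alpha, b = sol$b,
         n_sv = sum(sv))
  })
  structure(
    list(subproblems = subproblems, classes = cls, C = C, gamma = gamma),
    class = "svc_model"
  )
}

#' @export
print.svc_model <- function(x, ...) {
  cat("<svc_model> ", length(x$classes), " classes, ",
      length(x$subproblems), " binary subproblems, C = ", format(x$C),
      ", gamma = ", format(x$gamma), "\n", sep = "")
  invisible(x)
}

#' Decision values of the binary subproblems
#'
#' @param m An `svc_model`.
#' @param x Query feature matrix.
#' @return Numeric matrix, one row per query, one column per subproblem
#'   (named "classA/classB"); positive values vote for the first-named
#'   class.
#' @export
svc_decision_values <- function(m, x) {
  stopifnot(inherits(m, "svc_model"))
  x <- as_feature_matrix(x)
  vals <- vapply(m$subproblems, function(sp) {
    K <- rbf_kernel_matrix(x, sp$x, m$gamma)
    drop(K %*% (sp$alpha * sp$y)) + sp$b
  }, numeric(nrow(x)))
  vals <- matrix(vals, nrow = nrow(x))
  colnames(vals) <- vapply(m$subproblems,
                           function(sp) paste(sp$classes, collapse = "/"),
                           character(1))
  vals
}

#' @export
#' @param object An `svc_model`.
#' @param ... Unused.
#' @rdname svc_decision_values
#' @return For `predict`: factor of predicted labels. Vote ties are broken
#'   by the largest sum of absolute decision values accumulated by the tied
#'   classes, then by class order.
predict.svc_model <- function(object, x, ...) {
  x <- as_feature_matrix(x)
  dv <- svc_decision_values(object, x)
  k <- length(object$classes)
  votes <- matrix(0L, nrow(x), k, dimnames = list(NULL, object$classes))
  magn <- matrix(0, nrow(x), k, dimnames = list(NULL, object$classes))
  for (s in seq_along(object$subproblems)) {
    pr <- object$subproblems[[s]]$classes
    winner <- ifelse(dv[, s] >= 0, pr[1], pr[2])
    for (cl in pr) {
      w <- winner == cl
      votes[w, cl] <- votes[w, cl] + 1L
      magn[w, cl] <- magn[w, cl] + abs(dv[w, s])
    }
  }
  pred <- vapply(seq_len(nrow(x)), function(i) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1) top <- top[which.max(magn[i, top])]
    object$classes[top]
  }, character(1))
  factor(pred, levels = object$classes)
}
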