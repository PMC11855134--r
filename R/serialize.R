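# JSON round-tripping for fitted models: all stored patterns, coefficients
# and hyperparameters at full double precision, so a reloaded model
# reproduces predictions exactly.

#' Write a fitted model to JSON
#'
#' Supports `pnn_model`, `knn_model` and `svc_model`. The JSON carries a
#' `type` field plus every slot needed for exact reload with
#' [read_model_json()].
#'
#' @param m A fitted model object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(m, path) {
  payload <- if (inherits(m, "pnn_model")) {
    list(type = "pnn", patterns = m$patterns,
         labels = as.character(m$labels), classes = m$classes,
         sigma = m$sigma)
  } else if (inherits(m, "knn_model")) {
    list(type = "knn", patterns = m$patterns,
         labels = as.character(m$labels), classes = m$classes,
         k = m$k, offset = m$offset)
  } else if (inherits(m, "svc_model")) {
    list(type = "svc", classes = m$classes, C = m$C, gamma = m$gamma,
         subproblems = lapply(m$subproblems, function(sp) {
           list(classes = sp$classes, x = sp$x, y = sp$y,
                alpha = sp$alpha, b = sp$b, n_sv = sp$n_sv)
         }))
  } else stop("unsupported model class", call. = FALSE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", pretty = TRUE)
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path Path to a JSON file written by [write_model_json()].
#' @return The reconstructed model object.
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  as_mat <- function(x) {
    x <- as.matrix(x)
    colnames(x) <- c("concentration_uM", "exposure_h")[seq_len(ncol(x))]
    storage.mode(x) <- "double"
    x
  }
  switch(p$type,
    pnn = structure(
      list(patterns = as_mat(p$patterns),
           labels = factor(p$labels, levels = p$classes),
           classes = p$classes,
           class_counts = as.integer(table(factor(p$labels,
                                                  levels = p$classes))),
           sigma = p$sigma),
      class = "pnn_model"),
    knn = structure(
      list(patterns = as_mat(p$patterns),
           labels = factor(p$labels, levels = p$classes),
           classes = p$classes, k = as.integer(p$k), offset = p$offset),
      class = "knn_model"),
    svc = structure(
      list(subproblems = lapply(p$subproblems, function(sp) {
             list(classes = sp$classes, x = as_mat(sp$x),
                  y = as.numeric(sp$y), alpha = as.numeric(sp$alpha),
                  b = as.numeric(sp$b), n_sv = as.integer(sp$n_sv))
           }),
           classes = p$classes, C = p$C, gamma = p$gamma),
      class = "svc_model"),
    stop("unknown model type in ", path, call. = FALSE)
  )
}

#' Write predictions with posteriors as CSV
#'
#' @param m A fitted model.
#' @param x Query features in original units.
#' @param standardizer The `standardizer` used at training time.
#' @param path Output path.
#' @return The prediction data frame, invisibly.
#' @export
write_predictions_csv <- function(m, x, standardizer, path) {
  x <- as_feature_matrix(x)
  z <- apply_standardizer(standardizer, x)
  pred <- predict(m, z)
  df <- data.frame(concentration_uM = x[, 1], exposure_h = x[, 2],
                   predicted = as.character(pred))
  if (inherits(m, "pnn_model")) {
    post <- pnn_posterior(m, z)
    colnames(post) <- paste0("posterior_", colnames(post))
    df <- cbind(df, as.data.frame(post))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
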