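#' Confusion matrix
#'
#' Cross-tabulates true against predicted labels over a fixed class
#' ordering (rows = true class, columns = predicted class).
#'
#' @param truth,predicted Equal-length label vectors (character or factor).
#' @param classes Class ordering for the axes; defaults to the factor
#'   levels of `truth` (or [ploidy_classes()] when the labels are ploidy
#'   labels).
#' @return Integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (length(truth) == 0) stop("empty label vectors", call. = FALSE)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted differ in length", call. = FALSE)
  }
  if (is.null(classes)) {
    classes <- if (is.factor(truth)) levels(truth)
               else if (all(unique(truth) %in% PLOIDY_CLASSES)) PLOIDY_CLASSES
               else sort(unique(as.character(truth)))
  }
  truth <- as.character(truth); predicted <- as.character(predicted)
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad) > 0) {
    stop("label(s) outside the class set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  cm <- unclass(as.matrix(cm))
  names(dimnames(cm)) <- c("true", "predicted")
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' One-vs-rest counts for a class
#'
#' Reduces a multiclass confusion matrix to binary counts for one class:
#' TP is the diagonal cell, FP the rest of its column, FN the rest of its
#' row, TN everything else.
#'
#' @param cm A `confusion_matrix`.
#' @param class Class name or index.
#' @return Named integer vector `c(TP, FP, FN, TN)`.
#' @export
per_class_counts <- function(cm, class) {
  stopifnot(inherits(cm, "confusion_matrix"))
  j <- if (is.character(class)) match(class, colnames(cm)) else as.integer(class)
  if (is.na(j) || j < 1 || j > ncol(cm)) stop("unknown class", call. = FALSE)
  tp <- cm[j, j]
  fp <- sum(cm[, j]) - tp
  fn <- sum(cm[j, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

#' Performance metrics of a confusion matrix
#'
#' The five headline criteria: accuracy (percent of the trace over the
#' total), error rate (100 - accuracy), macro-averaged one-vs-rest
#' precision and recall, and the F1 score as the harmonic mean of the two
#' macro averages. A class never predicted (TP + FP = 0) contributes
#' precision 0 to the macro average; likewise an absent class contributes
#' recall 0.
#'
#' @param cm A `confusion_matrix`.
#' @return Object of class `metrics_report`: list with `accuracy` and
#'   `error_rate` (percent), `precision`, `recall`, `f1` (proportions), and
#'   the `confusion` matrix itself.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  accuracy <- sum(diag(cm)) / total * 100
  counts <- lapply(seq_len(ncol(cm)), function(j) per_class_counts(cm, j))
  prec <- vapply(counts, function(ct) {
    if (ct["TP"] + ct["FP"] == 0) 0 else ct["TP"] / (ct["TP"] + ct["FP"])
  }, numeric(1))
  rec <- vapply(counts, function(ct) {
    if (ct["TP"] + ct["FN"] == 0) 0 else ct["TP"] / (ct["TP"] + ct["FN"])
  }, numeric(1))
  precision <- mean(prec)
  recall <- mean(rec)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(
    list(accuracy = accuracy, error_rate = 100 - accuracy,
         precision = precision, recall = recall, f1 = f1, confusion = cm),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Accuracy   %.4f%%\n", x$accuracy))
  cat(sprintf("Error rate %.4f%%\n", x$error_rate))
  cat(sprintf("Precision  %.5f\n", x$precision))
  cat(sprintf("Recall     %.5f\n", x$recall))
  cat(sprintf("F1 Score   %.5f\n", x$f1))
  invisible(x)
}

#' Metrics table for several models and phases
#'
#' Assembles per-model, per-phase metrics reports into one long-format data
#' frame (criteria as columns), ready to serialize as CSV or JSON.
#'
#' @param reports Named list of `metrics_report` objects; names like
#'   "pnn_train".
#' @return Data frame with columns `model`, `phase`, `accuracy`,
#'   `error_rate`, `precision`, `recall`, `f1`.
#' @export
metrics_table <- function(reports) {
  stopifnot(length(reports) > 0, !is.null(names(reports)))
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    data.frame(model = paste(parts[-length(parts)], collapse = "_"),
               phase = parts[length(parts)],
               accuracy = r$accuracy, error_rate = r$error_rate,
               precision = r$precision, recall = r$recall, f1 = r$f1)
  })
  do.call(rbind, rows)
}
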