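#' Labeled ploidy dataset
#'
#' Container for a feature table of treatments (oryzalin concentration in
#' micromolar, exposure time in hours) with one ploidy class label per row.
#' The label set is closed: diploid, mixoploid, tetraploid.
#'
#' @param features Numeric matrix or data frame with columns
#'   `concentration_uM` and `exposure_h`, one row per experimental instance.
#' @param labels Character vector or factor of ploidy class labels, one per
#'   row of `features`.
#' @return An object of class `ploidy_dataset`: a list with elements
#'   `features` (numeric matrix) and `labels` (factor over the canonical
#'   class levels).
#' @examples
#' d <- ploidy_dataset(
#'   data.frame(concentration_uM = c(0, 60), exposure_h = c(24, 36)),
#'   c("diploid", "tetraploid")
#' )
#' class_counts(d)
#' @export
ploidy_dataset <- function(features, labels) {
  features <- as_feature_matrix(features)
  if (is.null(colnames(features))) {
    colnames(features) <- c("concentration_uM", "exposure_h")
  }
  if (!identical(colnames(features), c("concentration_uM", "exposure_h"))) {
    stop("features must have columns `concentration_uM`, `exposure_h`",
         call. = FALSE)
  }
  labels <- as.character(labels)
  if (nrow(features) != length(labels)) {
    stop("features and labels differ in length", call. = FALSE)
  }
  bad <- setdiff(unique(labels), PLOIDY_CLASSES)
  if (length(bad) > 0) {
    stop("unknown ploidy label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(features)) stop("features contain missing values", call. = FALSE)
  structure(
    list(features = features,
         labels = factor(labels, levels = PLOIDY_CLASSES)),
    class = "ploidy_dataset"
  )
}

#' @export
print.ploidy_dataset <- function(x, ...) {
  cat("<ploidy_dataset> ", nrow(x$features), " instances\n", sep = "")
  print(class_counts(x))
  invisible(x)
}

#' Number of instances in a ploidy dataset
#' @param d A `ploidy_dataset`.
#' @return Integer row count.
#' @export
n_instances <- function(d) nrow(d$features)

#' Per-class instance counts
#' @param d A `ploidy_dataset`.
#' @return Named integer vector over the canonical class ordering.
#' @export
class_counts <- function(d) table(d$labels)

#' Subset a ploidy dataset by row index
#' @param d A `ploidy_dataset`.
#' @param idx Integer row indices to keep.
#' @return A `ploidy_dataset` with the selected rows, in `idx` order.
#' @export
subset_dataset <- function(d, idx) {
  ploidy_dataset(d$features[idx, , drop = FALSE], as.character(d$labels[idx]))
}

#' Read a ploidy dataset from CSV
#'
#' Expects the exact header `concentration_uM,exposure_h,ploidy`; ploidy
#' values must be lowercase labels from the closed class set.
#'
#' @param path Path to a CSV file.
#' @return A `ploidy_dataset`.
#' @export
read_ploidy_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  req <- c("concentration_uM", "exposure_h", "ploidy")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) stop("empty dataset in ", path, call. = FALSE)
  for (col in c("concentration_uM", "exposure_h")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric `%s` at data row %d", col, bad[1]),
           call. = FALSE)
    }
    df[[col]] <- v
  }
  bad <- which(!df$ploidy %in% PLOIDY_CLASSES)
  if (length(bad) > 0) {
    stop(sprintf("unknown ploidy label %s at data row %d",
                 dQuote(df$ploidy[bad[1]]), bad[1]), call. = FALSE)
  }
  ploidy_dataset(df[, c("concentration_uM", "exposure_h")], df$ploidy)
}

#' Write a ploidy dataset to CSV
#'
#' Serializes with the exact header `concentration_uM,exposure_h,ploidy` and
#' full floating-point precision, so [read_ploidy_csv()] round-trips
#' losslessly.
#'
#' @param d A `ploidy_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ploidy_csv <- function(d, path) {
  stopifnot(inherits(d, "ploidy_dataset"))
  df <- data.frame(
    concentration_uM = format(d$features[, 1], digits = 17, trim = TRUE,
                              scientific = FALSE),
    exposure_h = format(d$features[, 2], digits = 17, trim = TRUE,
                        scientific = FALSE),
    ploidy = as.character(d$labels)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
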