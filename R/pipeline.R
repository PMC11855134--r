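#' Pipeline configuration
#'
#' Collects every setting of the end-to-end run: simulator parameters and
#' design, dataset sizes, hyperparameter grids, GA settings and seeds. All
#' randomness flows through the seeds recorded here; two runs with the same
#' configuration produce identical outputs.
#'
#' @param params [dose_response_params()] for the simulator.
#' @param grid Treatment design data frame; default
#'   [default_treatment_grid()].
#' @param replicates,explants Design of the simulated experiment
#'   (default 4 x 4).
#' @param per_class Balanced dataset size per class (default 24, i.e. 72
#'   rows).
#' @param train_per_class Training rows per class for the stratified split
#'   (default 19: 57 train / 15 test).
#' @param alpha Significance level of the PCA outlier screen
#'   (default 0.025).
#' @param sigma_grid,k_grid Hyperparameter grids for PNN / KNN
#'   leave-one-out selection.
#' @param svc_C,svc_gamma SVC box constraint and kernel width
#'   (`NULL` gamma = data-driven default, see [svc_fit()]).
#' @param knn_offset Positive-orthant shift for cosine KNN (default 3).
#' @param ga Optional [ga_config()]; `NULL` builds one from `seed` with
#'   package defaults.
#' @param seed Master seed; stage seeds (simulation, subsampling, split,
#'   GA) are derived from it deterministically.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(params = dose_response_params(),
                            grid = default_treatment_grid(),
                            replicates = 4, explants = 4,
                            per_class = 24, train_per_class = 19,
                            alpha = 0.025,
                            sigma_grid = c(0.25, 0.35, 0.5, 0.75, 1, 1.5, 2),
                            k_grid = c(1, 3, 5, 7, 9),
                            svc_C = 1, svc_gamma = NULL,
                            knn_offset = 3,
                            ga = NULL, seed = 1L) {
  check_seed(seed)
  seed <- as.integer(seed)
  # derived stage seeds, kept below 2^31
  stage_seed <- function(k) (seed * 1000L + k) %% .Machine$integer.max
  if (is.null(ga)) ga <- ga_config(seed = stage_seed(4L))
  stopifnot(inherits(params, "dose_response_params"),
            inherits(ga, "ga_config"))
  structure(
    list(params = params, grid = grid, replicates = replicates,
         explants = explants, per_class = per_class,
         train_per_class = train_per_class, alpha = alpha,
         sigma_grid = sigma_grid, k_grid = k_grid,
         svc_C = svc_C, svc_gamma = svc_gamma, knn_offset = knn_offset,
         ga = ga, seed = seed,
         sim_seed = stage_seed(1L), sample_seed = stage_seed(2L),
         split_seed = stage_seed(3L)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; `params` and `ga` may
#' be given as nested key-value maps, `grid` as a list with
#' `concentration_uM` and `exposure_h` arrays. Unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  known <- c("params", "grid", "replicates", "explants", "per_class",
             "train_per_class", "alpha", "sigma_grid", "k_grid", "svc_C",
             "svc_gamma", "knn_offset", "ga", "seed")
  bad <- setdiff(names(y), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(y$params)) y$params <- do.call(dose_response_params, y$params)
  if (!is.null(y$ga)) {
    if (!is.null(y$ga$bounds)) {
      y$ga$bounds <- matrix(unlist(y$ga$bounds), ncol = 2, byrow = TRUE,
                            dimnames = list(c("concentration_uM",
                                              "exposure_h"),
                                            c("lower", "upper")))
    }
    y$ga <- do.call(ga_config, y$ga)
  }
  if (!is.null(y$grid)) y$grid <- as.data.frame(y$grid)
  do.call(pipeline_config, y)
}

#' Run the end-to-end pipeline
#'
#' Simulate the experiment, assemble the balanced dataset, screen outliers,
#' split, standardize, select hyperparameters and fit the three
#' classifiers, evaluate them on both phases, rank them, and run the
#' PNN-coupled genetic algorithm for the optimal treatment. When
#' `output_dir` is given, persists the dataset CSV, split manifest, model
#' JSONs, the metrics table (CSV + JSON), the GA result and trace, and a
#' run manifest.
#'
#' @param cfg A [pipeline_config()].
#' @param output_dir Optional directory for run artifacts.
#' @return Object of class `run_report`: dataset summary, selected
#'   hyperparameters, metrics for 3 models x 2 phases, model ranking, and
#'   the `ga_result`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  records <- stage("simulate", simulate_experiment(
    cfg$grid, cfg$replicates, cfg$explants, cfg$params, cfg$sim_seed))
  dataset <- stage("assemble", assemble_balanced_dataset(
    records, cfg$per_class, cfg$sample_seed))
  screened <- stage("outlier_filter", pca_outlier_filter(dataset, cfg$alpha))
  split <- stage("split", stratified_split(
    screened$dataset, cfg$train_per_class, cfg$split_seed))
  std <- stage("standardize", fit_standardizer(split$train))
  ztrain <- apply_standardizer(std, split$train)
  ztest <- apply_standardizer(std, split$test)
  ytrain <- split$train$labels
  ytest <- split$test$labels

  sig <- stage("pnn", select_sigma(ztrain, ytrain, cfg$sigma_grid))
  pnn <- pnn_fit(ztrain, ytrain, sig$sigma)
  ksel <- stage("knn", select_k(ztrain, ytrain, cfg$k_grid, cfg$knn_offset))
  knn <- knn_fit(ztrain, ytrain, ksel$k, cfg$knn_offset)
  svc <- stage("svc", svc_fit(ztrain, ytrain, cfg$svc_C, cfg$svc_gamma))

  models <- list(pnn = pnn, knn = knn, svc = svc)
  reports <- stage("evaluate", {
    out <- list()
    for (nm in names(models)) {
      out[[paste0(nm, "_train")]] <- compute_metrics(confusion_matrix(
        ytrain, predict(models[[nm]], ztrain), PLOIDY_CLASSES))
      out[[paste0(nm, "_test")]] <- compute_metrics(confusion_matrix(
        ytest, predict(models[[nm]], ztest), PLOIDY_CLASSES))
    }
    out
  })
  metrics <- metrics_table(reports)
  ranking <- rank_models(metrics)
  ga_res <- stage("optimize", evolve(make_fitness(pnn, std), cfg$ga))

  report <- structure(
    list(class_counts = as.integer(class_counts(screened$dataset)),
         n_dataset = n_instances(dataset),
         outliers_removed = screened$removed,
         n_train = n_instances(split$train),
         n_test = n_instances(split$test),
         hyperparameters = list(sigma = sig$sigma, k = ksel$k,
                                svc_C = svc$C, svc_gamma = svc$gamma,
                                knn_offset = cfg$knn_offset),
         metrics = metrics, reports = reports, ranking = ranking,
         ga = ga_res, seed = cfg$seed),
    class = "run_report"
  )

  if (!is.null(output_dir)) {
    stage("persist", {
      dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
      fp <- function(...) file.path(output_dir, ...)
      write_ploidy_csv(dataset, fp("dataset.csv"))
      write_split_manifest(split, std, fp("split_manifest.json"))
      for (nm in names(models)) {
        write_model_json(models[[nm]], fp(paste0(nm, "_model.json")))
      }
      utils::write.csv(metrics, fp("metrics.csv"), row.names = FALSE)
      jsonlite::write_json(metrics, fp("metrics.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      jsonlite::write_json(
        list(best = as.list(ga_res$best), best_fitness = ga_res$best_fitness,
             generations = ga_res$generations, seed = ga_res$seed),
        fp("ga_result.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
      utils::write.csv(
        data.frame(generation = seq_along(ga_res$trace),
                   best_fitness = ga_res$trace),
        fp("ga_trace.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(seed = cfg$seed, n_dataset = report$n_dataset,
             outliers_removed = report$outliers_removed,
             hyperparameters = report$hyperparameters,
             ranking = ranking$model,
             files = c("dataset.csv", "split_manifest.json",
                       "pnn_model.json", "knn_model.json", "svc_model.json",
                       "metrics.csv", "metrics.json", "ga_result.json",
                       "ga_trace.csv")),
        fp("manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> dataset n =", x$n_dataset,
      "| train", x$n_train, "/ test", x$n_test, "\n")
  cat("  outliers removed:", length(x$outliers_removed), "\n")
  cat("  hyperparameters: sigma =", format(x$hyperparameters$sigma),
      ", k =", x$hyperparameters$k,
      ", C =", format(x$hyperparameters$svc_C),
      ", gamma =", format(x$hyperparameters$svc_gamma), "\n")
  print(x$metrics, digits = 6)
  cat("  ranking:", paste(x$ranking$model, collapse = " > "), "\n")
  print(x$ga)
  invisible(x)
}

#' Rank models by held-out performance
#'
#' Orders models by test accuracy, breaking ties by test F1, then training
#' accuracy; remaining ties preserve input order. The top-ranked model is
#' the one the optimizer stage should use.
#'
#' @param metrics Metrics data frame from [metrics_table()] (or a
#'   `run_report`'s `$metrics`), with both phases per model.
#' @return The per-model ranking as a data frame, best first, with columns
#'   `model`, `test_accuracy`, `test_f1`, `train_accuracy`.
#' @export
rank_models <- function(metrics) {
  if (inherits(metrics, "run_report")) metrics <- metrics$metrics
  need <- c("model", "phase", "accuracy", "f1")
  if (!all(need %in% names(metrics))) {
    stop("metrics table is missing required columns", call. = FALSE)
  }
  models <- unique(metrics$model)
  pick <- function(m, ph, col) {
    v <- metrics[metrics$model == m & metrics$phase == ph, col]
    if (length(v) != 1) stop("missing metrics for model ", m, call. = FALSE)
    v
  }
  tab <- data.frame(
    model = models,
    test_accuracy = vapply(models, pick, numeric(1), ph = "test",
                           col = "accuracy"),
    test_f1 = vapply(models, pick, numeric(1), ph = "test", col = "f1"),
    train_accuracy = vapply(models, pick, numeric(1), ph = "train",
                            col = "accuracy")
  )
  ord <- order(-tab$test_accuracy, -tab$test_f1, -tab$train_accuracy,
               seq_len(nrow(tab)))
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  tab
}
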