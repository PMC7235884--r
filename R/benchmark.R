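#' Benchmark run configuration
#'
#' Bundles every setting of a full benchmark run — data source, the
#' preprocessing plan, the network and optimizer configurations, the HOG
#' geometry, the baseline list, and the fold plan parameters — under one
#' global seed from which all stage seeds are derived deterministically.
#' A run is fully reconstructible from the persisted configuration.
#'
#' @param manifest,image_dir paths to a manifest CSV and its image
#'   directory, or `NULL` when `synthetic` is used.
#' @param synthetic a [synth_config()] to generate data in place of a
#'   manifest, or `NULL`.
#' @param output_dir directory for report files.
#' @param plan a [preprocess_plan()].
#' @param net an [akdl_config()].
#' @param train a [train_config()].
#' @param hog a [hog_config()].
#' @param models character subset of `c("akdl", "svm", "rf", "knn")`.
#' @param folds fold count (default 10).
#' @param stratified stratified folds (default `TRUE`).
#' @param augment augment training data inside each fold (default `TRUE`;
#'   has no effect on balanced data under the default minority-only plan).
#' @param seed global integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(manifest = NULL, image_dir = NULL, synthetic = NULL,
                       output_dir = tempfile("akdl_run_"),
                       plan = preprocess_plan(), net = akdl_config(),
                       train = train_config(), hog = hog_config(),
                       models = c("akdl", "svm", "rf", "knn"),
                       folds = 10L, stratified = TRUE, augment = TRUE,
                       seed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  check_scalar_num(folds, "folds", lower = 2, integer = TRUE)
  check_scalar_num(seed, "seed", integer = TRUE)
  if (is.null(synthetic) && is.null(manifest))
    stop_config("manifest",
                "is required unless synthetic data is requested")
  # the plan standardizes to whatever the network consumes
  plan$target_size <- net$input_size
  structure(list(manifest = manifest, image_dir = image_dir,
                 synthetic = synthetic, output_dir = output_dir,
                 plan = plan, net = net, train = train, hog = hog,
                 models = models, folds = as.integer(folds),
                 stratified = isTRUE(stratified),
                 augment = isTRUE(augment), seed = as.integer(seed)),
            class = "run_config")
}

benchmark_log <- function(fmt, ..., debug = FALSE) {
  message(sprintf(paste0("[akdl] ", fmt), ...))
}

#' Run the full benchmark: AK-DL against the HOG baselines
#'
#' Loads (or generates) the dataset, builds one fold plan, cross-validates
#' each requested model under it, and writes: `report.csv` (one row per
#' model with the mean metrics and wall-clock training time),
#' `report.json` (per-fold detail), `roc_<model>.csv` ROC points of each
#' fold, and `config.json`, the resolved configuration.  Metric outputs
#' are deterministic given the configuration; the `train_seconds` column
#' is wall-clock and excluded from that contract.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `reports` (named [cross_validate()]
#'   results), `table` (the report data.frame) and `files`.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    syn$seed <- derive_seed(seed, 1L)
    benchmark_log("generating synthetic dataset (n_per_class=%d, separation=%.2f, seed=%d)",
                  syn$n_per_class, syn$separation, syn$seed)
    dataset <- generate_dataset(syn)
  } else {
    if (is.null(config$manifest) || !file.exists(config$manifest))
      stop("configuration error: manifest file not found and no synthetic data requested",
           call. = FALSE)
    benchmark_log("loading manifest %s", config$manifest)
    dataset <- load_manifest(config$manifest, config$image_dir)
  }

  fold_plan <- make_folds(dataset$labels, k = config$folds,
                          seed = derive_seed(seed, 2L),
                          stratified = config$stratified)
  benchmark_log("fold plan: %d folds over %d samples", config$folds,
                length(dataset))

  recipes <- list()
  for (m in config$models) {
    recipes[[m]] <- if (m == "akdl") {
      net <- config$net; tr <- config$train
      net$init_seed <- derive_seed(seed, 10L)
      tr$shuffle_seed <- derive_seed(seed, 11L)
      akdl_recipe(net, tr, config$plan)
    } else {
      baseline_recipe(baseline_spec(m, seed = derive_seed(seed, 20L)),
                      config$hog)
    }
  }

  reports <- list()
  for (m in config$models) {
    benchmark_log("cross-validating %s ...", m)
    reports[[m]] <- cross_validate(recipes[[m]], dataset, fold_plan,
                                   augment = config$augment,
                                   preprocess = config$plan)
    benchmark_log("%s: mean Acc %.3f, AUC %.3f (%.1f s)", m,
                  reports[[m]]$mean[["Acc"]], reports[[m]]$mean[["AUC"]],
                  reports[[m]]$train_seconds)
  }

  tab <- do.call(rbind, lapply(names(reports), function(m) {
    r <- reports[[m]]
    data.frame(model = m, Acc = r$mean[["Acc"]], Sens = r$mean[["Sens"]],
               Spec = r$mean[["Spec"]], Prec = r$mean[["Prec"]],
               MCC = r$mean[["MCC"]], AUC = r$mean[["AUC"]],
               train_seconds = round(r$train_seconds, 1))
  }))

  files <- list(report_csv = file.path(config$output_dir, "report.csv"),
                report_json = file.path(config$output_dir, "report.json"),
                config_json = file.path(config$output_dir, "config.json"))
  write.csv(tab, files$report_csv, row.names = FALSE)
  jsonlite::write_json(
    lapply(reports, function(r)
      list(model = r$model_name, mean = as.list(r$mean),
           folds = r$folds, train_seconds = r$train_seconds)),
    files$report_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  strip_classes <- function(x)
    if (is.list(x)) lapply(unclass(x), strip_classes) else x
  cfg_out <- strip_classes(config)
  jsonlite::write_json(cfg_out, files$config_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  for (m in names(reports)) {
    roc_file <- file.path(config$output_dir, sprintf("roc_%s.csv", m))
    pts <- do.call(rbind, lapply(seq_along(reports[[m]]$roc), function(f)
      cbind(fold = f, reports[[m]]$roc[[f]])))
    write.csv(pts, roc_file, row.names = FALSE)
    files[[paste0("roc_", m)]] <- roc_file
  }
  benchmark_log("report written to %s", files$report_csv)
  invisible(list(reports = reports, table = tab, files = files))
}

#' Reload a persisted benchmark configuration
#'
#' Reads the `config.json` written by [run_benchmark()] and reconstructs
#' the [run_config()], so a run can be reproduced exactly from its own
#' artifacts (metrics are deterministic given the configuration).
#'
#' @param path path to a `config.json`.
#' @param output_dir optional new output directory (defaults to the
#'   persisted one).
#' @return A [run_config()].
#' @export
load_run_config <- function(path, output_dir = NULL) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  keep <- function(fn, l) l[intersect(names(l), names(formals(fn)))]
  run_config(
    manifest = j$manifest, image_dir = j$image_dir,
    synthetic = if (!is.null(j$synthetic))
      do.call(synth_config, keep(synth_config, j$synthetic)),
    output_dir = output_dir %||% j$output_dir,
    plan = do.call(preprocess_plan, keep(preprocess_plan, j$plan)),
    net = do.call(akdl_config, keep(akdl_config, j$net)),
    train = do.call(train_config, keep(train_config, j$train)),
    hog = do.call(hog_config, keep(hog_config, j$hog)),
    models = j$models, folds = j$folds, stratified = j$stratified,
    augment = j$augment, seed = j$seed)
}
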