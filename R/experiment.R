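#' Configure a reproducible fusion experiment
#'
#' Bundles every knob of a generate/fuse/optimize/evaluate run. The same
#' config (including `seed`) replays the run exactly; [run_experiment()]
#' writes a resolved-config snapshot alongside its outputs for that purpose.
#'
#' @param strategy Fusion strategy: `"cfs"`, `"awfs"`, `"mowfs"` or
#'   `"fowfs"`.
#' @param optimizer Metaheuristic for the optimized strategies: `"ajs"`,
#'   `"ga"` or `"pso"`.
#' @param classifier Classifier kind for both the wrapper cost and the final
#'   evaluation: `"dt"`, `"nb"`, `"mlp"` or `"svm"`.
#' @param seed Global seed; optimizer, splits and classifier seeds all
#'   derive from it.
#' @param input Optional path to a feature-table CSV
#'   ([read_feature_table()]); when `NULL`, data come from the synthetic
#'   generator.
#' @param synth A [synth_config()] used when `input` is `NULL`; its seed is
#'   overridden by `seed`.
#' @param pop_size,max_iter Optimizer budget (defaults 10 and 50).
#' @param test_frac Final held-out fraction, split off before any weight
#'   optimization (default 0.2, stratified).
#' @param validation_frac Inner validation fraction of the wrapper MSE cost
#'   (default 0.3).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(strategy = c("cfs", "awfs", "mowfs", "fowfs"),
                              optimizer = c("ajs", "ga", "pso"),
                              classifier = c("svm", "dt", "nb", "mlp"),
                              seed = 1L, input = NULL,
                              synth = synth_config(
                                n_samples = 300, n_classes = 7,
                                block_dims = c(20L, 20L, 20L),
                                informative_frac = 0.2, effect_size = 1.5),
                              pop_size = 10L, max_iter = 50L,
                              test_frac = 0.2, validation_frac = 0.3) {
  structure(list(strategy = match.arg(strategy),
                 optimizer = match.arg(optimizer),
                 classifier = match.arg(classifier),
                 seed = as.integer(seed), input = input, synth = synth,
                 pop_size = as.integer(pop_size),
                 max_iter = as.integer(max_iter),
                 test_frac = test_frac, validation_frac = validation_frac),
            class = "experiment_config")
}

#' Read an experiment configuration from JSON or YAML
#'
#' Keys mirror the arguments of [experiment_config()]; nested `synth` keys
#' mirror [synth_config()]. Unknown keys are rejected.
#'
#' @param path `.json`, `.yml` or `.yaml` file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- setdiff(names(formals(experiment_config)), "synth")
  extra <- setdiff(names(raw), c(known, "synth"))
  if (length(extra) > 0)
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  args <- raw[intersect(names(raw), known)]
  if (!is.null(raw$synth))
    args$synth <- do.call(synth_config, raw$synth)
  do.call(experiment_config, args)
}

# Restrict a multi-view dataset to a row subset.
subset_dataset <- function(dataset, idx) {
  multiview_dataset(
    lapply(dataset$blocks, function(b)
      feature_block(b$extractor_id, b$matrix[idx, , drop = FALSE])),
    dataset$labels[idx])
}

optimizer_config_for <- function(config) {
  switch(config$optimizer,
         ajs = ajs_config(pop_size = config$pop_size,
                          max_iter = config$max_iter, seed = config$seed),
         ga = ga_config(pop_size = config$pop_size,
                        max_iter = config$max_iter, seed = config$seed),
         pso = pso_config(pop_size = config$pop_size,
                          max_iter = config$max_iter, seed = config$seed))
}

#' Run a full fusion experiment
#'
#' Generates (or loads) a multi-view dataset, splits off a stratified test
#' fold before any weight learning, learns the requested fusion strategy on
#' the training fold, applies the learned weights and ranked-selection mask
#' to all rows, fits the classifier on the training fold of the final fused
#' matrix and scores the test fold. A degenerate ranked selection (no weight
#' above 0.5) falls back to the full weighted set with a warning.
#'
#' When `out_dir` is given, writes `config.json` (resolved-config snapshot),
#' `metrics.json`, `weights.csv` and — for optimized strategies —
#' `trace.csv` (per-iteration best cost).
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return Invisibly, a list with `metrics` (a `metrics_report`), `weights`
#'   (weights data frame), `strategy`, `selected_dim`, `fused_dim`, `result`
#'   (an `optimization_result` or `NULL`) and `files`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (!is.null(config$input)) {
    dataset <- read_feature_table(config$input)
  } else {
    sc <- config$synth
    sc$seed <- config$seed
    dataset <- generate_dataset(sc)$dataset
  }
  cspec <- classifier_spec(config$classifier, seed = config$seed)
  split <- withr::with_seed(config$seed,
                            stratified_split(dataset$labels,
                                             test_frac = config$test_frac))
  train_ds <- subset_dataset(dataset, split$train)

  weights <- NULL; mask <- NULL; result <- NULL
  if (config$strategy == "cfs") {
    weights <- weight_scheme("model", rep(1, length(dataset$blocks)))
  } else if (config$strategy == "awfs") {
    weights <- awfs(train_ds, cspec, seed = config$seed)$weights
  } else {
    ocfg <- optimizer_config_for(config)
    optimize_fun <- if (config$strategy == "mowfs") mowfs else fowfs
    fit <- tryCatch(
      optimize_fun(train_ds, cspec, ocfg,
                   validation_frac = config$validation_frac,
                   cost_seed = config$seed),
      degenerate_selection_error = function(e) {
        warning("ranked selection is empty; falling back to the full ",
                "weighted feature set", call. = FALSE)
        list(weights = e$weights, mask = NULL, result = e$result)
      })
    weights <- fit$weights
    mask <- fit$mask
    result <- fit$result
  }

  fused <- if (weights$level == "model")
    apply_model_weights(dataset, weights, strategy = toupper(config$strategy))
  else apply_feature_weights(dataset, weights,
                             strategy = toupper(config$strategy))
  fused_dim <- ncol(fused$matrix)
  if (!is.null(mask)) fused <- mask_columns(fused, expand_mask(mask, dataset))
  metrics <- train_eval(fused, dataset$labels, cspec, seed = config$seed,
                        split = split)
  weights_df <- weights_table(weights, dataset, mask = mask)

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    snapshot <- config
    snapshot$synth <- unclass(snapshot$synth)
    jsonlite::write_json(unclass(snapshot),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, null = "null", digits = 10)
    jsonlite::write_json(
      list(strategy = toupper(config$strategy),
           optimizer = if (config$strategy %in% c("mowfs", "fowfs"))
             config$optimizer else NULL,
           classifier = config$classifier, seed = config$seed,
           fused_dim = fused_dim, selected_dim = ncol(fused$matrix),
           accuracy = metrics$accuracy, precision = metrics$precision,
           sensitivity = metrics$sensitivity, f1 = metrics$f1,
           auc = metrics$auc, n_test = metrics$n_test),
      file.path(out_dir, "metrics.json"),
      auto_unbox = TRUE, null = "null", digits = 10)
    utils::write.csv(weights_df, file.path(out_dir, "weights.csv"),
                     row.names = FALSE)
    files <- c("config.json", "metrics.json", "weights.csv")
    if (!is.null(result)) {
      write_trace_csv(result, file.path(out_dir, "trace.csv"))
      files <- c(files, "trace.csv")
    }
    files <- file.path(out_dir, files)
  }
  invisible(list(metrics = metrics, weights = weights_df,
                 strategy = toupper(config$strategy),
                 selected_dim = ncol(fused$matrix), fused_dim = fused_dim,
                 result = result, files = files))
}
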