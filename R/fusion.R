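#' Construct a feature block
#'
#' A feature block is one extractor's output: an `n_samples x d` numeric
#' matrix tagged with the extractor's identity. Typical widths for the
#' pre-trained backbones emulated here are 512 (VGG16-like) and 1024
#' (EfficientNet-B0-like, ResNet50-like).
#'
#' @param extractor_id Character label, e.g. `"vgg16-like"`.
#' @param matrix Numeric matrix, one row per sample.
#' @return An object of class `feature_block`.
#' @export
feature_block <- function(extractor_id, matrix) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (nrow(matrix) < 1L || ncol(matrix) < 1L)
    stop("a feature block needs at least one sample and one column")
  if (!all(is.finite(matrix)))
    stop("feature block contains non-finite entries")
  structure(list(extractor_id = as.character(extractor_id),
                 matrix = matrix, d = ncol(matrix)),
            class = "feature_block")
}

#' Bundle feature blocks and class labels into a multi-view dataset
#'
#' @param blocks List of [feature_block()]s sharing a common row count.
#' @param labels Factor (or coercible) of class labels, one per sample.
#' @return An object of class `multiview_dataset` with elements `blocks`,
#'   `labels`, `n_samples`, `n_classes`.
#' @export
multiview_dataset <- function(blocks, labels) {
  stopifnot(length(blocks) >= 1L,
            all(vapply(blocks, inherits, logical(1L), "feature_block")))
  n <- vapply(blocks, function(b) nrow(b$matrix), integer(1L))
  if (length(unique(n)) != 1L)
    stop("all blocks must have the same number of rows")
  labels <- droplevels(as.factor(labels))
  if (length(labels) != n[1L])
    stop("labels length does not match the number of samples")
  if (nlevels(labels) < 2L)
    stop("at least two classes are required")
  structure(list(blocks = blocks, labels = labels,
                 n_samples = n[1L], n_classes = nlevels(labels)),
            class = "multiview_dataset")
}

#' @export
print.multiview_dataset <- function(x, ...) {
  cat(sprintf("<multiview_dataset> %d samples, %d classes, blocks: %s\n",
              x$n_samples, x$n_classes,
              paste(sprintf("%s(%d)",
                            vapply(x$blocks, `[[`, character(1L), "extractor_id"),
                            block_dims(x)), collapse = " + ")))
  invisible(x)
}

#' Block widths of a multi-view dataset
#' @param dataset A [multiview_dataset()].
#' @return Integer vector of per-block column counts.
#' @export
block_dims <- function(dataset) {
  vapply(dataset$blocks, function(b) ncol(b$matrix), integer(1L))
}

#' Construct a fusion weight scheme
#'
#' Weights live in `[0, 1]`. At `level = "model"` there is one scalar per
#' extractor block; at `level = "feature"` one weight per fused column
#' (`sum(block_dims)` in total, 512 + 1024 + 1024 = 2560 at the default
#' widths).
#'
#' @param level `"model"` or `"feature"`.
#' @param weights Numeric vector in `[0, 1]`.
#' @return An object of class `weight_scheme`.
#' @export
weight_scheme <- function(level = c("model", "feature"), weights) {
  level <- match.arg(level)
  weights <- as.numeric(weights)
  if (!all(is.finite(weights)) || any(weights < 0) || any(weights > 1))
    stop("weights must lie in [0, 1]")
  structure(list(level = level, weights = weights), class = "weight_scheme")
}

#' Column provenance of a fused matrix
#' @noRd
fused_provenance <- function(dataset) {
  data.frame(
    extractor_id = rep(vapply(dataset$blocks, `[[`, character(1L),
                              "extractor_id"), block_dims(dataset)),
    column = unlist(lapply(block_dims(dataset), seq_len)),
    stringsAsFactors = FALSE)
}

new_fused_feature_set <- function(matrix, strategy, weights_used = NULL,
                                  mask = NULL, provenance) {
  structure(list(matrix = matrix, strategy = strategy,
                 weights_used = weights_used, mask = mask,
                 provenance = provenance),
            class = "fused_feature_set")
}

#' @export
print.fused_feature_set <- function(x, ...) {
  cat(sprintf("<fused_feature_set> strategy %s: %d samples x %d columns%s\n",
              x$strategy, nrow(x$matrix), ncol(x$matrix),
              if (!is.null(x$mask)) " (ranked subset)" else ""))
  invisible(x)
}

#' Concatenate feature blocks (CFS)
#'
#' The combined feature set: blocks stacked column-wise in block order, no
#' weighting, no selection. Widths 512/1024/1024 give a 2560-column fused
#' set.
#'
#' @param dataset A [multiview_dataset()].
#' @return A `fused_feature_set` with strategy `"CFS"`.
#' @export
concat_blocks <- function(dataset) {
  stopifnot(inherits(dataset, "multiview_dataset"))
  m <- do.call(cbind, lapply(dataset$blocks, `[[`, "matrix"))
  new_fused_feature_set(m, "CFS", provenance = fused_provenance(dataset))
}

#' Apply block-level fusion weights
#'
#' Scales every column of block `b` by the scalar weight `w[b]`, then
#' concatenates. All-ones weights reproduce [concat_blocks()] exactly.
#'
#' @param dataset A [multiview_dataset()].
#' @param w A [weight_scheme()] at model level, length = number of blocks.
#' @param strategy Strategy tag recorded on the result (default `"MOWFS"`).
#' @return A `fused_feature_set`.
#' @export
apply_model_weights <- function(dataset, w, strategy = "MOWFS") {
  stopifnot(inherits(dataset, "multiview_dataset"),
            inherits(w, "weight_scheme"))
  if (w$level != "model")
    stop("apply_model_weights needs a model-level weight scheme")
  if (length(w$weights) != length(dataset$blocks))
    stop("need one weight per block")
  m <- do.call(cbind, Map(function(b, wi) b$matrix * wi,
                          dataset$blocks, w$weights))
  new_fused_feature_set(m, strategy, weights_used = w,
                        provenance = fused_provenance(dataset))
}

#' Apply per-feature fusion weights
#'
#' Multiplies fused column `i` by `w[i]`; the weight vector spans all blocks
#' in concatenation order.
#'
#' @param dataset A [multiview_dataset()].
#' @param w A [weight_scheme()] at feature level, length = `sum(block_dims)`.
#' @param strategy Strategy tag recorded on the result (default `"FOWFS"`).
#' @return A `fused_feature_set`.
#' @export
apply_feature_weights <- function(dataset, w, strategy = "FOWFS") {
  stopifnot(inherits(dataset, "multiview_dataset"),
            inherits(w, "weight_scheme"))
  if (w$level != "feature")
    stop("apply_feature_weights needs a feature-level weight scheme")
  total <- sum(block_dims(dataset))
  if (length(w$weights) != total)
    stop(sprintf("need %d weights (one per fused column), got %d",
                 total, length(w$weights)))
  fused <- concat_blocks(dataset)
  m <- sweep(fused$matrix, 2L, w$weights, `*`)
  new_fused_feature_set(m, strategy, weights_used = w,
                        provenance = fused$provenance)
}

#' Highest-ranked selection: keep weights strictly above a threshold
#'
#' The ranked feature set keeps entries whose optimized weight exceeds 0.5;
#' the comparison is strict, so a weight of exactly 0.5 is dropped. Selecting
#' nothing is an error (callers such as [run_experiment()] catch it and fall
#' back to the full set with a warning).
#'
#' @param w A [weight_scheme()].
#' @param threshold Selection threshold (default 0.5).
#' @return An object of class `selection_mask`: logical `keep` aligned with
#'   `w$weights`, plus the level and threshold.
#' @export
select_ranked <- function(w, threshold = 0.5) {
  stopifnot(inherits(w, "weight_scheme"))
  keep <- w$weights > threshold
  if (!any(keep))
    stop(structure(
      class = c("degenerate_selection_error", "error", "condition"),
      list(message = "no weight exceeds the selection threshold; the ranked set is empty",
           call = sys.call(-1L))))
  structure(list(keep = keep, level = w$level, threshold = threshold),
            class = "selection_mask")
}

#' Expand a selection mask to fused-column flags
#'
#' Model-level masks flag whole blocks; this expands each block flag over
#' that block's columns so the mask aligns with the fused matrix.
#'
#' @param mask A `selection_mask`.
#' @param dataset The [multiview_dataset()] the mask refers to.
#' @return Logical vector over fused columns.
#' @export
expand_mask <- function(mask, dataset) {
  stopifnot(inherits(mask, "selection_mask"))
  if (mask$level == "feature") return(mask$keep)
  rep(mask$keep, block_dims(dataset))
}

#' Reduce a fused set to its selected columns
#'
#' @param fused A `fused_feature_set`.
#' @param keep Logical vector over fused columns.
#' @return A `fused_feature_set` restricted to the kept columns.
#' @export
mask_columns <- function(fused, keep) {
  stopifnot(inherits(fused, "fused_feature_set"),
            length(keep) == ncol(fused$matrix))
  out <- fused
  out$matrix <- fused$matrix[, keep, drop = FALSE]
  out$provenance <- fused$provenance[keep, , drop = FALSE]
  out$mask <- keep
  out
}

#' Search space for fusion-weight optimization
#'
#' Model-level weights give one decision variable per block; feature-level
#' weights one per fused column (2560 at widths 512/1024/1024). Bounds are
#' `[0, 1]` in every dimension.
#'
#' @param dataset A [multiview_dataset()].
#' @param level `"model"` or `"feature"`.
#' @return A [search_space()].
#' @export
fusion_space <- function(dataset, level = c("model", "feature")) {
  level <- match.arg(level)
  dim <- if (level == "model") length(dataset$blocks)
         else sum(block_dims(dataset))
  search_space(dim, 0, 1)
}

#' Classifier mean-squared-error cost of a fusion weight vector
#'
#' The wrapper objective minimized by MOWFS/FOWFS: weight the fused feature
#' matrix, split the provided rows into an inner stratified train/validation
#' partition, fit the classifier on the training part, and return the mean
#' squared error between one-hot true labels and predicted class-probability
#' vectors on the validation part. Deterministic for a fixed `seed`
#' (the global RNG stream is left untouched, so optimizer randomness is not
#' perturbed by cost evaluations). For the SVM the probabilities are a
#' softmax over one-vs-rest aggregated decision values rather than Platt
#' calibration, keeping the cost smooth in the weights.
#'
#' @param w A [weight_scheme()]; its level selects block or per-feature
#'   weighting.
#' @param dataset A [multiview_dataset()] (training rows only; keep the final
#'   test split outside).
#' @param spec A [classifier_spec()].
#' @param validation_frac Fraction of rows held out for the inner validation
#'   fold (default 0.3, stratified by class).
#' @param seed Integer controlling the inner split and any classifier
#'   randomness.
#' @return Scalar validation MSE in `[0, 1]`.
#' @export
mse_cost <- function(w, dataset, spec, validation_frac = 0.3, seed = 1L) {
  stopifnot(inherits(w, "weight_scheme"),
            inherits(dataset, "multiview_dataset"))
  fused <- if (w$level == "model") apply_model_weights(dataset, w)
           else apply_feature_weights(dataset, w)
  withr::with_seed(seed, {
    split <- stratified_split(dataset$labels, test_frac = validation_frac)
    fit <- fit_classifier(spec,
                          fused$matrix[split$train, , drop = FALSE],
                          dataset$labels[split$train], calibrate = FALSE)
    probs <- cost_probs(fit, fused$matrix[split$test, , drop = FALSE])
    onehot <- stats::model.matrix(~ y - 1,
                                  data.frame(y = dataset$labels[split$test]))
    mean((onehot - probs)^2)
  })
}

#' Adaptive weighted feature set (AWFS)
#'
#' Block weights start uniform in (0, 1) and are then adapted to each block's
#' standalone validation accuracy, rescaled by the best block's accuracy so
#' the strongest extractor receives weight 1 and weaker ones proportionally
#' less.
#'
#' @param dataset A [multiview_dataset()].
#' @param spec A [classifier_spec()].
#' @param seed Integer seed for the accuracy evaluations.
#' @return List with `weights` (model-level [weight_scheme()]), `fused`
#'   (the weighted `fused_feature_set`, strategy `"AWFS"`) and
#'   `block_accuracy`.
#' @export
awfs <- function(dataset, spec, seed = 1L) {
  stopifnot(inherits(dataset, "multiview_dataset"))
  acc <- vapply(dataset$blocks, function(b) {
    ds <- multiview_dataset(list(b), dataset$labels)
    train_eval(concat_blocks(ds), ds$labels, spec, seed = seed)$accuracy
  }, numeric(1L))
  wts <- acc / max(acc)
  w <- weight_scheme("model", wts)
  list(weights = w,
       fused = apply_model_weights(dataset, w, strategy = "AWFS"),
       block_accuracy = acc)
}

#' Model-based optimized weighted feature set (MOWFS)
#'
#' Treats the block weights (w1, w2, w3 for three extractors) as decision
#' variables in `[0, 1]` and minimizes the classifier MSE cost with the
#' chosen metaheuristic. Blocks whose optimized weight exceeds 0.5 form the
#' highest-ranked feature set; the returned fused set is the weighted
#' concatenation restricted to those blocks.
#'
#' @param dataset A [multiview_dataset()] (training rows).
#' @param spec A [classifier_spec()] driving the MSE cost.
#' @param config An optimizer configuration ([ajs_config()], [ga_config()]
#'   or [pso_config()]).
#' @param validation_frac Inner validation fraction for [mse_cost()].
#' @param cost_seed Seed fixing the inner split across cost evaluations.
#' @return List with `weights`, `mask` (block-level `selection_mask`),
#'   `fused` (weighted, ranked-reduced set), and `result` (the
#'   `optimization_result`).
#' @export
mowfs <- function(dataset, spec, config = ajs_config(),
                  validation_frac = 0.3, cost_seed = 1L) {
  space <- fusion_space(dataset, "model")
  objective <- function(x)
    mse_cost(weight_scheme("model", x), dataset, spec,
             validation_frac = validation_frac, seed = cost_seed)
  result <- run_optimizer(objective, space, config)
  w <- weight_scheme("model", result$best_position)
  mask <- select_ranked_or_rethrow(w, result)
  fused <- mask_columns(apply_model_weights(dataset, w),
                        expand_mask(mask, dataset))
  list(weights = w, mask = mask, fused = fused, result = result)
}

#' Feature-based optimized weighted feature set (FOWFS)
#'
#' One decision variable per fused column (2560 at the default widths);
#' the optimizer minimizes the same classifier MSE cost and columns with
#' optimized weight above 0.5 are retained for final classification.
#'
#' @inheritParams mowfs
#' @return List with `weights` (feature-level), `mask`, `fused` and
#'   `result`.
#' @export
fowfs <- function(dataset, spec, config = ajs_config(),
                  validation_frac = 0.3, cost_seed = 1L) {
  space <- fusion_space(dataset, "feature")
  objective <- function(x)
    mse_cost(weight_scheme("feature", x), dataset, spec,
             validation_frac = validation_frac, seed = cost_seed)
  result <- run_optimizer(objective, space, config)
  w <- weight_scheme("feature", result$best_position)
  mask <- select_ranked_or_rethrow(w, result)
  fused <- mask_columns(apply_feature_weights(dataset, w), mask$keep)
  list(weights = w, mask = mask, fused = fused, result = result)
}

# Ranked selection that, on an empty result, attaches the learned weights
# and optimizer result to the condition so orchestration code can fall back
# to the full weighted set.
select_ranked_or_rethrow <- function(w, result) {
  tryCatch(select_ranked(w),
           degenerate_selection_error = function(e) {
             e$weights <- w
             e$result <- result
             stop(e)
           })
}

#' Export a weight scheme (and optional mask) as a data frame / CSV
#'
#' @param w A [weight_scheme()].
#' @param dataset The [multiview_dataset()] the weights refer to.
#' @param mask Optional `selection_mask`.
#' @param path Optional CSV output path.
#' @return Data frame with `index`, `extractor_id`, `weight`, `selected`.
#' @export
weights_table <- function(w, dataset, mask = NULL, path = NULL) {
  stopifnot(inherits(w, "weight_scheme"))
  ids <- vapply(dataset$blocks, `[[`, character(1L), "extractor_id")
  if (w$level == "model") {
    df <- data.frame(index = seq_along(w$weights), extractor_id = ids,
                     weight = w$weights)
  } else {
    df <- cbind(data.frame(index = seq_along(w$weights)),
                fused_provenance(dataset))
    df$weight <- w$weights
  }
  df$selected <- if (is.null(mask)) NA else mask$keep
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
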