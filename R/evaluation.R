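#' Compute multiclass metrics from a confusion matrix
#'
#' Precision, sensitivity (recall) and F1 are computed per class and
#' macro-averaged (unweighted mean over classes). A class never predicted
#' has precision 0; an empty class has recall 0.
#'
#' @param confusion Square contingency table, true classes in rows,
#'   predicted in columns.
#' @return List with `accuracy`, `precision`, `sensitivity`, `f1` and a
#'   `per_class` data frame.
#' @export
confusion_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  tp <- diag(confusion)
  pred_n <- colSums(confusion)
  true_n <- rowSums(confusion)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(true_n > 0, tp / true_n, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(accuracy = sum(tp) / sum(confusion),
       precision = mean(precision),
       sensitivity = mean(recall),
       f1 = mean(f1),
       per_class = data.frame(class = rownames(confusion) %||%
                                as.character(seq_along(tp)),
                              precision = precision, sensitivity = recall,
                              f1 = f1, row.names = NULL))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Macro one-vs-rest AUC
#'
#' Area under the ROC curve for each class against the rest, averaged with
#' equal class weight. Classes absent from `labels` are skipped with a
#' warning.
#'
#' @param scores `n x C` matrix of class scores or probabilities, columns
#'   named (or ordered) by class level.
#' @param labels Factor of true classes.
#' @return Scalar macro-averaged AUC in `[0, 1]`.
#' @export
auc_ovr <- function(scores, labels) {
  labels <- as.factor(labels)
  scores <- as.matrix(scores)
  lev <- if (!is.null(colnames(scores))) colnames(scores) else levels(labels)
  stopifnot(length(lev) == ncol(scores))
  aucs <- vapply(seq_along(lev), function(j) {
    present <- labels == lev[j]
    if (!any(present) || all(present)) {
      warning(sprintf("class '%s' absent from one side; skipped", lev[j]))
      return(NA_real_)
    }
    as.numeric(pROC::auc(pROC::roc(response = present,
                                   predictor = scores[, j],
                                   levels = c(FALSE, TRUE),
                                   direction = "<", quiet = TRUE)))
  }, numeric(1L))
  mean(aucs, na.rm = TRUE)
}

#' Train a classifier on a fused set and score a held-out fold
#'
#' Stratified split of the fused rows, fit on the training fold, metrics on
#' the test fold: accuracy, macro precision/sensitivity/F1 and macro
#' one-vs-rest AUC. Deterministic for a fixed `seed`.
#'
#' @param fused A `fused_feature_set` (or bare matrix).
#' @param labels Factor of class labels aligned with the rows.
#' @param spec A [classifier_spec()].
#' @param test_frac Held-out fraction (default 0.2, stratified).
#' @param seed Integer seed for the split and classifier randomness.
#' @param split Optional pre-made split (list with `train` and `test` index
#'   vectors); overrides `test_frac`.
#' @return A `metrics_report`: list with the scalar metrics, `per_class`,
#'   `confusion` and `n_test`.
#' @export
train_eval <- function(fused, labels, spec, test_frac = 0.2, seed = 1L,
                       split = NULL) {
  x <- if (inherits(fused, "fused_feature_set")) fused$matrix else as.matrix(fused)
  labels <- droplevels(as.factor(labels))
  stopifnot(nrow(x) == length(labels))
  withr::with_seed(seed, {
    if (is.null(split)) split <- stratified_split(labels, test_frac = test_frac)
    fit <- fit_classifier(spec, x[split$train, , drop = FALSE],
                          labels[split$train])
    probs <- predict_probs(fit, x[split$test, , drop = FALSE])
    truth <- labels[split$test]
    pred <- factor(levels(labels)[max.col(probs, ties.method = "first")],
                   levels = levels(labels))
    confusion <- table(truth = truth, predicted = pred)
    out <- confusion_metrics(confusion)
    out$auc <- auc_ovr(probs, truth)
    out$confusion <- confusion
    out$n_test <- length(truth)
    structure(out, class = "metrics_report")
  })
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> accuracy %.4f | macro precision %.4f |",
                     " sensitivity %.4f | F1 %.4f | AUC %.4f (n_test = %d)\n"),
              x$accuracy, x$precision, x$sensitivity, x$f1, x$auc, x$n_test))
  invisible(x)
}

#' Construct a Friedman rank table
#'
#' Holds per-method rank sums `R` over `N` datasets for `k` methods, as used
#' by the Friedman statistic. Rank sums must total `N * k * (k + 1) / 2`.
#'
#' @param R Numeric vector of rank sums, one per method.
#' @param N Number of datasets (blocks).
#' @return An object of class `rank_table` with `R`, `N`, `k`.
#' @export
rank_table <- function(R, N) {
  R <- as.numeric(R)
  k <- length(R)
  stopifnot(k >= 2L, N >= 1L, all(is.finite(R)))
  expected <- N * k * (k + 1) / 2
  if (abs(sum(R) - expected) > 1e-8)
    stop(sprintf("rank sums total %g but must total N*k*(k+1)/2 = %g",
                 sum(R), expected))
  structure(list(R = R, N = as.integer(N), k = as.integer(k)),
            class = "rank_table")
}

#' Rank methods within each dataset
#'
#' Builds the rank table for the Friedman comparison from an accuracy matrix
#' (methods in rows, datasets in columns). Within each dataset the best
#' method receives rank `k` and the worst rank 1, so stronger methods carry
#' larger rank sums; ties share the average of their ranks.
#'
#' @param accuracy Numeric matrix, `k` methods x `N` datasets.
#' @return A [rank_table()].
#' @export
rank_methods <- function(accuracy) {
  accuracy <- as.matrix(accuracy)
  if (any(is.na(accuracy))) stop("accuracy table has missing cells")
  ranks <- apply(accuracy, 2L, rank)   # rank 1 = lowest accuracy
  rank_table(rowSums(ranks), N = ncol(accuracy))
}

#' Friedman rank-sum statistic
#'
#' `FM = 12 / (N * k * (k + 1)) * sum(R^2) - 3 * N * (k + 1)` for rank sums
#' `R` over `N` datasets and `k` methods. With `paper_rounding = TRUE` the
#' leading coefficient is truncated to three decimal places before the
#' multiplication, replicating a common hand-computed presentation of the
#' statistic (e.g. `0.083 * 1922 - 144 = 15.526` for `R = (32, 27, 13)`,
#' `N = 12`, `k = 3`); the default is full precision.
#'
#' @param table A [rank_table()].
#' @param paper_rounding Truncate the coefficient `12/(N*k*(k+1))` to three
#'   decimals before use (default `FALSE`).
#' @return Scalar Friedman statistic.
#' @export
friedman_statistic <- function(table, paper_rounding = FALSE) {
  stopifnot(inherits(table, "rank_table"))
  coefficient <- 12 / (table$N * table$k * (table$k + 1))
  if (paper_rounding) coefficient <- trunc(coefficient * 1000) / 1000
  coefficient * sum(table$R^2) - 3 * table$N * (table$k + 1)
}
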