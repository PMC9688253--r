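#' Specify a classifier for the evaluation harness and wrapper cost
#'
#' Four classifier families are supported: decision tree (`"dt"`, rpart),
#' Gaussian naive Bayes (`"nb"`, e1071), multi-layer perceptron (`"mlp"`,
#' single-hidden-layer nnet) and support vector machine (`"svm"`, e1071 RBF
#' kernel with probability estimates). All expose class-probability
#' predictions, as required by the MSE cost and one-vs-rest AUC.
#'
#' Note that tree and naive-Bayes fits are invariant to per-feature positive
#' rescaling, so they cannot feel fusion weights; use `"mlp"` or `"svm"` as
#' the wrapper cost classifier. The SVM is fitted with `scale = FALSE` for
#' the same reason: internal standardization would undo the weights under
#' optimization.
#'
#' @param kind One of `"dt"`, `"nb"`, `"mlp"`, `"svm"`.
#' @param ... Hyperparameters passed on to the underlying fitting function
#'   (e.g. `size` for the MLP, `cost`/`gamma` for the SVM).
#' @param seed Integer seed applied around the fit (relevant for the MLP's
#'   random initial weights and the SVM's internal probability calibration).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("dt", "nb", "mlp", "svm"), ...,
                            seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, hyper = list(...), seed = as.integer(seed)),
            class = "classifier_spec")
}

# Fit the classifier named by `spec` on matrix x / factor y; returns an
# object predict_probs() understands. Callers are responsible for seeding.
# `calibrate = FALSE` skips the SVM's Platt probability model (cost-path
# fits only need decision values).
fit_classifier <- function(spec, x, y, calibrate = TRUE) {
  stopifnot(inherits(spec, "classifier_spec"))
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("training fold contains a single class")
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  df <- data.frame(y = y, x, check.names = FALSE)
  fit <- switch(spec$kind,
    dt = do.call(rpart::rpart,
                 c(list(y ~ ., data = df, method = "class"), spec$hyper)),
    nb = {
      # call through a wrapper so naiveBayes sees clean argument symbols
      # (do.call would splice the data into the deparsed call)
      nb_fit <- function(x, y, ...) e1071::naiveBayes(x = x, y = y, ...)
      do.call(nb_fit, c(list(x = x, y = y), spec$hyper))
    },
    mlp = {
      hyper <- utils::modifyList(list(size = 5L, maxit = 200L,
                                      decay = 1e-3, MaxNWts = 1e5,
                                      trace = FALSE), spec$hyper)
      do.call(nnet::nnet, c(list(y ~ ., data = df), hyper))
    },
    svm = do.call(e1071::svm,
                  c(list(x = x, y = y, probability = calibrate,
                         scale = FALSE), spec$hyper)))
  structure(list(kind = spec$kind, fit = fit, levels = levels(y)),
            class = "jellyfuse_fit")
}

# n x C class-probability matrix, columns in training-level order.
predict_probs <- function(model, x) {
  stopifnot(inherits(model, "jellyfuse_fit"))
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  df <- as.data.frame(x)
  p <- switch(model$kind,
    dt = stats::predict(model$fit, df, type = "prob"),
    nb = stats::predict(model$fit, x, type = "raw"),
    mlp = {
      raw <- stats::predict(model$fit, df, type = "raw")
      if (ncol(raw) == 1L) cbind(1 - raw[, 1L], raw[, 1L]) else raw
    },
    svm = {
      pred <- stats::predict(model$fit, x, probability = TRUE)
      attr(pred, "probabilities")
    })
  p <- as.matrix(p)
  if (is.null(colnames(p)) || !all(model$levels %in% colnames(p))) {
    colnames(p) <- model$levels
  }
  p <- p[, model$levels, drop = FALSE]
  p / pmax(rowSums(p), .Machine$double.eps)
}

# Smooth class-probability estimates for the wrapper cost. For the SVM,
# Platt calibration (probability = TRUE) runs an internal cross-validation
# whose refitting makes the cost landscape rugged under small weight
# changes; the wrapper cost instead uses a softmax over one-vs-rest
# aggregated pairwise decision values, which is deterministic and smooth in
# the fusion weights. Other classifiers already give smooth probabilities.
cost_probs <- function(model, x) {
  if (model$kind != "svm") return(predict_probs(model, x))
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  pred <- stats::predict(model$fit, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  lev <- model$levels
  scores <- matrix(0, nrow = nrow(dv), ncol = length(lev),
                   dimnames = list(NULL, lev))
  for (nm in colnames(dv)) {
    pair <- strsplit(nm, "/", fixed = TRUE)[[1L]]
    scores[, pair[1L]] <- scores[, pair[1L]] + dv[, nm]
    scores[, pair[2L]] <- scores[, pair[2L]] - dv[, nm]
  }
  e <- exp(scores - apply(scores, 1L, max))
  e / rowSums(e)
}

#' Stratified train/test split of class labels
#'
#' Splits sample indices so that each class is represented in both folds in
#' proportion to its frequency. Errors if any class is too rare to appear in
#' both folds.
#'
#' @param labels Factor of class labels.
#' @param test_frac Fraction of each class assigned to the test fold.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, test_frac = 0.2) {
  labels <- as.factor(labels)
  stopifnot(test_frac > 0, test_frac < 1)
  test <- unlist(lapply(levels(labels), function(cl) {
    idx <- which(labels == cl)
    n_test <- round(length(idx) * test_frac)
    if (n_test < 1L || n_test >= length(idx))
      stop(sprintf("class '%s' is too rare to stratify at test_frac = %g",
                   cl, test_frac))
    sample(idx, n_test)
  }))
  list(train = sort(setdiff(seq_along(labels), test)), test = sort(test))
}
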