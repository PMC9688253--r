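#' Load the packaged fused-vs-ranked validation accuracy tables
#'
#' Published validation accuracies of the eight fusion strategies (CFS,
#' AWFS, MOWFS and FOWFS variants under GA/PSO/AJS) on the two dermoscopy
#' benchmarks (HAM 10000, BCN 20000), one table per classifier (DT, NB,
#' MLP, SVM). Ranked-set dimensionalities are kept verbatim (block sums such
#' as `"512+1024"` for model-level selection, plain counts for feature-level
#' selection).
#'
#' @param path CSV path; defaults to the copy shipped with the package.
#' @return Data frame with columns `classifier`, `dataset`, `strategy`,
#'   `dim_fused`, `acc_fused`, `dim_ranked`, `acc_ranked`.
#' @export
load_validation_tables <- function(path = system.file(
    "extdata", "validation_accuracy_tables.csv", package = "jellyfuse")) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(dim_ranked = "character"))
}

#' Load the packaged recognition-accuracy tables
#'
#' Published recognition accuracy of the three standalone extractor models
#' and the eight fusion strategies, per classifier and dataset. Feeds
#' [rank_methods()] / [friedman_statistic()] worked examples.
#'
#' @param path CSV path; defaults to the packaged copy.
#' @return Data frame with columns `dataset`, `classifier`, `method`,
#'   `accuracy`.
#' @export
load_recognition_tables <- function(path = system.file(
    "extdata", "recognition_accuracy.csv", package = "jellyfuse")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Load the narrative improvement claims
#'
#' Improvement figures (percentage points over CFS) quoted in the source
#' publication's narrative alongside its accuracy tables. Several quoted
#' figures disagree with their own table cells; [delta_report()] flags each
#' claim as consistent or not rather than forcing agreement.
#'
#' @param path CSV path; defaults to the packaged copy.
#' @return Data frame with columns `classifier`, `dataset`, `strategy`,
#'   `set` (`fused`/`ranked`), `claimed_pp`, `source`.
#' @export
load_printed_claims <- function(path = system.file(
    "extdata", "printed_improvement_claims.csv", package = "jellyfuse")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# "512+1024" -> 1536; plain counts pass through.
parse_dim <- function(x) {
  vapply(strsplit(as.character(x), "\\+"),
         function(p) sum(as.numeric(trimws(p))), numeric(1L))
}

#' Fused-vs-ranked improvement report over CFS
#'
#' For every classifier/dataset/strategy row of a validation-accuracy table,
#' computes the improvement over the CFS baseline in percentage points,
#' separately for the fused feature set and the highest-ranked feature set:
#' `delta = (accuracy - accuracy_CFS) * 100`, rounded to 2 decimal places.
#' When narrative claims are supplied, each claim is checked against the
#' recomputed delta and flagged (`consistent`) at a 0.005 pp rounding
#' tolerance.
#'
#' @param results Validation table as returned by
#'   [load_validation_tables()].
#' @param claims Optional claims table ([load_printed_claims()]).
#' @return An object of class `comparison_report`: list with `table` (the
#'   per-row deltas plus parsed dimensionalities) and `claims` (claim check,
#'   or `NULL`).
#' @examples
#' rep <- delta_report()
#' subset(rep$table, classifier == "DT" & dataset == "HAM 10000" &
#'        strategy == "MOWFS-AJS")
#' @export
delta_report <- function(results = load_validation_tables(),
                         claims = load_printed_claims()) {
  needed <- c("classifier", "dataset", "strategy",
              "acc_fused", "acc_ranked")
  stopifnot(all(needed %in% names(results)))
  groups <- split(results, list(results$classifier, results$dataset),
                  drop = TRUE)
  tab <- do.call(rbind, lapply(groups, function(g) {
    cfs <- g[g$strategy == "CFS", ]
    if (nrow(cfs) != 1L)
      stop("each classifier/dataset group needs exactly one CFS row")
    g$delta_fused_pp <- round((g$acc_fused - cfs$acc_fused) * 100, 2)
    g$delta_ranked_pp <- round((g$acc_ranked - cfs$acc_ranked) * 100, 2)
    g
  }))
  rownames(tab) <- NULL
  tab$dim_fused_n <- parse_dim(tab$dim_fused)
  tab$dim_ranked_n <- parse_dim(tab$dim_ranked)

  claim_check <- NULL
  if (!is.null(claims) && nrow(claims) > 0) {
    claim_check <- claims
    key <- function(d) paste(d$classifier, d$dataset, d$strategy)
    idx <- match(key(claims), key(tab))
    if (anyNA(idx)) stop("claim refers to a strategy missing from the table")
    claim_check$computed_pp <- ifelse(
      claims$set == "fused", tab$delta_fused_pp[idx], tab$delta_ranked_pp[idx])
    claim_check$consistent <-
      abs(claim_check$computed_pp - claim_check$claimed_pp) <= 0.005
  }
  structure(list(table = tab, claims = claim_check),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> improvements over CFS (percentage points)\n")
  print(x$table[, c("classifier", "dataset", "strategy",
                    "delta_fused_pp", "delta_ranked_pp", "dim_ranked")],
        row.names = FALSE)
  if (!is.null(x$claims)) {
    n_bad <- sum(!x$claims$consistent)
    cat(sprintf("narrative claims checked: %d, inconsistent with tables: %d\n",
                nrow(x$claims), n_bad))
  }
  invisible(x)
}
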