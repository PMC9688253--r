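#' Define a box-constrained search space
#'
#' A search space is the axis-aligned box in which an optimizer moves its
#' candidate solutions. For fusion-weight optimization the box is
#' `[0, 1]^dim`: one dimension per extractor block (model-level weights) or
#' one per feature column (feature-level weights).
#'
#' @param dim Positive integer, number of decision variables.
#' @param lower,upper Numeric scalars or length-`dim` vectors of per-dimension
#'   bounds; scalars are recycled. Every lower bound must be strictly below
#'   its upper bound.
#' @return An object of class `search_space` with elements `dim`, `lower`,
#'   `upper`.
#' @examples
#' search_space(3)                      # unit cube
#' search_space(2, lower = -1, upper = 1)
#' @export
search_space <- function(dim, lower = 0, upper = 1) {
  stopifnot(length(dim) == 1L, is.finite(dim), dim >= 1, dim == round(dim))
  dim <- as.integer(dim)
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (!all(is.finite(lower)) || !all(is.finite(upper)))
    stop("search_space bounds must be finite")
  if (!all(lower < upper))
    stop("every lower bound must be strictly below its upper bound")
  structure(list(dim = dim, lower = lower, upper = upper),
            class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat(sprintf("<search_space> %d dims, bounds [%s, %s]%s\n", x$dim,
              format(x$lower[1]), format(x$upper[1]),
              if (length(unique(x$lower)) > 1 || length(unique(x$upper)) > 1)
                " (per-dimension)" else ""))
  invisible(x)
}

#' Reflect out-of-bounds coordinates to the opposite bound
#'
#' Boundary handling for the jellyfish search: a coordinate that leaves the
#' box re-enters from the opposite side, i.e. `x > upper` becomes
#' `x - upper + lower` and `x < lower` becomes `x - lower + upper`, applied
#' repeatedly until the coordinate is in range. In-range coordinates are
#' untouched.
#'
#' @param position Numeric vector of length `space$dim`.
#' @param space A [search_space()].
#' @return Numeric vector inside `[lower, upper]`.
#' @examples
#' sp <- search_space(1)
#' wrap_bounds(1.2, sp)   # 0.2
#' wrap_bounds(-0.3, sp)  # 0.7
#' @export
wrap_bounds <- function(position, space) {
  stopifnot(inherits(space, "search_space"))
  if (length(position) != space$dim)
    stop("position length does not match search space dimension")
  if (!all(is.finite(position)))
    stop("non-finite coordinate cannot be wrapped")
  x <- as.numeric(position)
  repeat {
    hi <- x > space$upper
    lo <- x < space$lower
    if (!any(hi) && !any(lo)) break
    x[hi] <- x[hi] - space$upper[hi] + space$lower[hi]
    x[lo] <- x[lo] - space$lower[lo] + space$upper[lo]
  }
  x
}

# Uniform population initialization over the box.
init_population <- function(space, pop_size) {
  m <- matrix(stats::runif(pop_size * space$dim), nrow = pop_size)
  sweep(sweep(m, 2L, space$upper - space$lower, `*`), 2L, space$lower, `+`)
}

# Evaluate an objective over the rows of a position matrix, insisting on
# finite costs (a non-finite cost would corrupt best-so-far bookkeeping).
eval_costs <- function(objective, positions) {
  costs <- apply(positions, 1L, objective)
  if (!all(is.finite(costs)))
    stop("objective returned a non-finite cost; optimization aborted")
  as.numeric(costs)
}

new_optimization_result <- function(best_position, best_cost, trace, n_evals,
                                    optimizer) {
  structure(list(best_position = best_position, best_cost = best_cost,
                 trace = trace, n_evals = n_evals, optimizer = optimizer),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("<optimization_result> %s: best cost %.6g after %d evaluations (%d iterations)\n",
              x$optimizer, x$best_cost, x$n_evals, length(x$trace)))
  invisible(x)
}

#' Export a convergence trace as CSV
#'
#' Writes the per-iteration best-so-far cost of an optimizer run as a
#' two-column CSV (`iteration`, `best_cost`).
#'
#' @param result An `optimization_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(result, path) {
  stopifnot(inherits(result, "optimization_result"))
  utils::write.csv(
    data.frame(iteration = seq_along(result$trace), best_cost = result$trace),
    path, row.names = FALSE)
  invisible(path)
}
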