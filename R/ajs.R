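#' Configuration for the artificial jellyfish search optimizer
#'
#' The artificial jellyfish search (AJS) is a swarm metaheuristic that
#' alternates a global drift toward the incumbent best ("ocean current")
#' with local swarm motions (passive jitter and pairwise active moves),
#' switched by a decaying random time-control function.
#'
#' @param pop_size Swarm size (default 10).
#' @param max_iter Number of iterations (default 50).
#' @param phi Distribution coefficient of the ocean-current drift; controls
#'   how strongly the swarm mean is subtracted from the best location
#'   (default 3).
#' @param omega Motion coefficient: passive-step length as a fraction of the
#'   box span (default 0.1).
#' @param c0 Time-control switch threshold in (0,1); the ocean-current branch
#'   fires when the time-control draw is at least `c0` (default 0.5).
#' @param seed Integer seed for the optimizer's random stream, or `NULL` to
#'   continue the current stream.
#' @return An object of class `c("ajs_config", "optimizer_config")`.
#' @export
ajs_config <- function(pop_size = 10, max_iter = 50, phi = 3, omega = 0.1,
                       c0 = 0.5, seed = NULL) {
  stopifnot(pop_size >= 2, max_iter >= 1, phi > 0, omega > 0,
            c0 > 0, c0 < 1)
  structure(list(pop_size = as.integer(pop_size),
                 max_iter = as.integer(max_iter),
                 phi = phi, omega = omega, c0 = c0, seed = seed),
            class = c("ajs_config", "optimizer_config"))
}

#' Ocean-current direction toward the incumbent best
#'
#' The global drift vector is the best location minus a randomly attenuated
#' swarm mean: `best - phi * u * colMeans(positions)` with a single scalar
#' draw `u ~ Uniform(0,1)`.
#'
#' @param positions Matrix of current swarm locations (one row per member).
#' @param best_position Incumbent best location.
#' @param phi Distribution coefficient, positive.
#' @param draw Uniform random source `function(n)`; replaceable for testing.
#' @return Numeric direction vector of length `ncol(positions)`.
#' @export
ocean_current <- function(positions, best_position, phi, draw = stats::runif) {
  if (is.null(dim(positions)) || nrow(positions) == 0L)
    stop("ocean_current requires a non-empty population")
  stopifnot(phi > 0, length(best_position) == ncol(positions))
  best_position - phi * draw(1L) * colMeans(positions)
}

#' Drift a location along the ocean current
#'
#' @param position Current location.
#' @param current Direction vector from [ocean_current()].
#' @param draw Uniform random source.
#' @return `position + u * current` with scalar `u ~ Uniform(0,1)`.
#' @export
drift_step <- function(position, current, draw = stats::runif) {
  if (length(position) != length(current))
    stop("position and current differ in length")
  position + draw(1L) * current
}

#' Passive swarm motion around a location
#'
#' Jitters each coordinate by `omega * u_d * (upper_d - lower_d)` with an
#' independent uniform draw per dimension. The result may leave the box;
#' [wrap_bounds()] restores feasibility.
#'
#' @param position Current location.
#' @param space A [search_space()].
#' @param omega Motion coefficient.
#' @param draw Uniform random source.
#' @return Jittered location (possibly out of bounds).
#' @export
passive_step <- function(position, space, omega, draw = stats::runif) {
  if (length(position) != space$dim)
    stop("position length does not match search space dimension")
  position + omega * draw(space$dim) * (space$upper - space$lower)
}

#' Active swarm motion toward a better partner
#'
#' Member `i` compares costs with a partner `j`: it moves toward `j` when its
#' own cost is no better (`cost_i >= cost_j`, ties included) and away
#' otherwise, by a random fraction of the separation vector.
#'
#' @param pos_i,pos_j Locations of the member and its partner.
#' @param cost_i,cost_j Their objective values (smaller is better).
#' @param draw Uniform random source.
#' @return Updated location for member `i`.
#' @export
active_step <- function(pos_i, pos_j, cost_i, cost_j, draw = stats::runif) {
  stopifnot(length(pos_i) == length(pos_j),
            is.finite(cost_i), is.finite(cost_j))
  direction <- if (cost_i >= cost_j) pos_j - pos_i else pos_i - pos_j
  pos_i + draw(1L) * direction
}

#' Time-control function of the jellyfish search
#'
#' `|(1 - t/max_iter) * (2u - 1)|` with `u ~ Uniform(0,1)`: a random value in
#' `[0, 1)` whose envelope decays linearly with the iteration count, so the
#' swarm drifts with the ocean current early and swarms locally late. The
#' absolute value keeps the stated `(0, 1)` range (the raw product spans
#' `(-1, 1)`).
#'
#' @param t Current iteration, `1 <= t <= max_iter`.
#' @param max_iter Total iterations.
#' @param draw Uniform random source.
#' @return Scalar in `[0, 1)`; exactly 0 at `t == max_iter`.
#' @export
time_control <- function(t, max_iter, draw = stats::runif) {
  if (t < 1 || t > max_iter) stop("iteration index out of range")
  abs((1 - t / max_iter) * (2 * draw(1L) - 1))
}

#' Artificial jellyfish search over a box-constrained objective
#'
#' Runs the jellyfish search loop: each member, at each iteration, draws a
#' time-control value `fTC`; if `fTC >= c0` it drifts along the ocean
#' current toward the incumbent best; otherwise, with probability `fTC` it
#' takes a passive jitter step and with the complementary probability an
#' active step toward a random better-or-worse partner. Positions are wrapped
#' back into the box; each member keeps the candidate only when it is not
#' worse than its current location (greedy per-member acceptance, the
#' "minimum-cost" selection step of the wrapper loop), and the best-so-far
#' solution is tracked.
#'
#' @param objective Function mapping a position vector to a finite scalar
#'   cost; smaller is better.
#' @param space A [search_space()].
#' @param config An [ajs_config()].
#' @return An `optimization_result` with `best_position`, `best_cost`, the
#'   per-iteration best-so-far `trace` (monotone non-increasing), and
#'   `n_evals`.
#' @examples
#' sp <- search_space(2, -1, 1)
#' res <- ajs_optimize(function(x) sum(x^2), sp, ajs_config(seed = 1))
#' res$best_cost
#' @export
ajs_optimize <- function(objective, space, config = ajs_config()) {
  stopifnot(inherits(space, "search_space"), inherits(config, "ajs_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  pop <- config$pop_size
  positions <- init_population(space, pop)
  costs <- eval_costs(objective, positions)
  n_evals <- pop
  ibest <- which.min(costs)
  best_position <- positions[ibest, ]
  best_cost <- costs[ibest]
  trace <- numeric(config$max_iter)

  for (t in seq_len(config$max_iter)) {
    for (i in seq_len(pop)) {
      ftc <- time_control(t, config$max_iter)
      if (ftc >= config$c0) {
        current <- ocean_current(positions, best_position, config$phi)
        candidate <- drift_step(positions[i, ], current)
      } else if (stats::runif(1L) > (1 - ftc)) {
        candidate <- passive_step(positions[i, ], space, config$omega)
      } else {
        j <- sample(seq_len(pop)[-i], 1L)
        candidate <- active_step(positions[i, ], positions[j, ],
                                 costs[i], costs[j])
      }
      candidate <- wrap_bounds(candidate, space)
      cost <- objective(candidate)
      if (!is.finite(cost))
        stop("objective returned a non-finite cost; optimization aborted")
      n_evals <- n_evals + 1L
      if (cost <= costs[i]) {
        positions[i, ] <- candidate
        costs[i] <- cost
      }
      if (cost < best_cost) {
        best_cost <- cost
        best_position <- candidate
      }
    }
    trace[t] <- best_cost
  }
  new_optimization_result(best_position, best_cost, trace, n_evals, "ajs")
}
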