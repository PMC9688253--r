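#' Configuration for the real-coded genetic algorithm baseline
#'
#' Roulette-wheel selection on inverted cost, uniform arithmetic crossover,
#' per-gene Gaussian mutation and single-member elitism.
#'
#' @param pop_size Population size (default 10).
#' @param max_iter Number of generations (default 50).
#' @param crossover_prob Probability a parent pair is crossed (default 0.8).
#' @param mutation_prob Per-gene mutation probability (default 0.1).
#' @param mutation_sd Mutation standard deviation as a fraction of the box
#'   span (default 0.1).
#' @param elitism Number of best members copied unchanged (default 1).
#' @param seed Integer seed or `NULL`.
#' @return An object of class `c("ga_config", "optimizer_config")`.
#' @export
ga_config <- function(pop_size = 10, max_iter = 50, crossover_prob = 0.8,
                      mutation_prob = 0.1, mutation_sd = 0.1, elitism = 1,
                      seed = NULL) {
  stopifnot(pop_size >= 2, max_iter >= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            mutation_sd > 0, elitism >= 0, elitism < pop_size)
  structure(list(pop_size = as.integer(pop_size),
                 max_iter = as.integer(max_iter),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 mutation_sd = mutation_sd,
                 elitism = as.integer(elitism), seed = seed),
            class = c("ga_config", "optimizer_config"))
}

#' Configuration for the particle swarm baseline
#'
#' Canonical global-best PSO with damped inertia and velocities clamped to
#' the box span.
#'
#' @param pop_size Number of particles (default 10).
#' @param max_iter Number of iterations (default 50).
#' @param inertia Initial inertia weight (default 1).
#' @param damping Multiplicative inertia decay per iteration (default 0.99).
#' @param c1 Personal (cognitive) learning coefficient (default 1.5).
#' @param c2 Global (social) learning coefficient (default 2.0).
#' @param seed Integer seed or `NULL`.
#' @return An object of class `c("pso_config", "optimizer_config")`.
#' @export
pso_config <- function(pop_size = 10, max_iter = 50, inertia = 1,
                       damping = 0.99, c1 = 1.5, c2 = 2.0, seed = NULL) {
  stopifnot(pop_size >= 2, max_iter >= 1, inertia > 0,
            damping > 0, damping <= 1, c1 >= 0, c2 >= 0)
  structure(list(pop_size = as.integer(pop_size),
                 max_iter = as.integer(max_iter),
                 inertia = inertia, damping = damping, c1 = c1, c2 = c2,
                 seed = seed),
            class = c("pso_config", "optimizer_config"))
}

# Roulette-wheel selection probabilities for minimization: fitness is the
# cost shortfall from the worst member, plus a floor so an all-equal
# population degrades to uniform selection rather than 0/0.
roulette_probs <- function(costs, eps = 1e-12) {
  fitness <- (max(costs) - costs) + eps
  fitness / sum(fitness)
}

#' Real-coded genetic algorithm over a box-constrained objective
#'
#' @inheritParams ajs_optimize
#' @param config A [ga_config()].
#' @return An `optimization_result`.
#' @export
ga_optimize <- function(objective, space, config = ga_config()) {
  stopifnot(inherits(space, "search_space"), inherits(config, "ga_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  pop <- config$pop_size
  span <- space$upper - space$lower
  positions <- init_population(space, pop)
  costs <- eval_costs(objective, positions)
  n_evals <- pop
  ibest <- which.min(costs)
  best_position <- positions[ibest, ]
  best_cost <- costs[ibest]
  trace <- numeric(config$max_iter)

  for (t in seq_len(config$max_iter)) {
    probs <- roulette_probs(costs)
    offspring <- matrix(0, nrow = pop, ncol = space$dim)
    # elites survive unchanged
    elite_idx <- order(costs)[seq_len(config$elitism)]
    n_elite <- config$elitism
    if (n_elite > 0) offspring[seq_len(n_elite), ] <- positions[elite_idx, ]
    k <- n_elite
    while (k < pop) {
      parents <- sample.int(pop, 2L, replace = TRUE, prob = probs)
      p1 <- positions[parents[1L], ]
      p2 <- positions[parents[2L], ]
      if (stats::runif(1L) < config$crossover_prob) {
        a <- stats::runif(space$dim)   # uniform arithmetic crossover
        c1 <- a * p1 + (1 - a) * p2
        c2 <- a * p2 + (1 - a) * p1
      } else {
        c1 <- p1
        c2 <- p2
      }
      for (child in list(c1, c2)) {
        if (k >= pop) break
        mut <- stats::runif(space$dim) < config$mutation_prob
        if (any(mut))
          child[mut] <- child[mut] +
            stats::rnorm(sum(mut), 0, config$mutation_sd * span[mut])
        child <- pmin(pmax(child, space$lower), space$upper)
        k <- k + 1L
        offspring[k, ] <- child
      }
    }
    positions <- offspring
    costs <- eval_costs(objective, positions)
    n_evals <- n_evals + pop
    ibest <- which.min(costs)
    if (costs[ibest] < best_cost) {
      best_cost <- costs[ibest]
      best_position <- positions[ibest, ]
    }
    trace[t] <- best_cost
  }
  new_optimization_result(best_position, best_cost, trace, n_evals, "ga")
}

#' Particle swarm optimization over a box-constrained objective
#'
#' @inheritParams ajs_optimize
#' @param config A [pso_config()].
#' @return An `optimization_result`.
#' @export
pso_optimize <- function(objective, space, config = pso_config()) {
  stopifnot(inherits(space, "search_space"), inherits(config, "pso_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  pop <- config$pop_size
  span <- space$upper - space$lower
  positions <- init_population(space, pop)
  velocities <- matrix(0, nrow = pop, ncol = space$dim)
  costs <- eval_costs(objective, positions)
  n_evals <- pop

  pbest_pos <- positions
  pbest_cost <- costs
  ibest <- which.min(costs)
  best_position <- positions[ibest, ]
  best_cost <- costs[ibest]
  w <- config$inertia
  trace <- numeric(config$max_iter)

  for (t in seq_len(config$max_iter)) {
    for (i in seq_len(pop)) {
      r1 <- stats::runif(space$dim)
      r2 <- stats::runif(space$dim)
      v <- w * velocities[i, ] +
        config$c1 * r1 * (pbest_pos[i, ] - positions[i, ]) +
        config$c2 * r2 * (best_position - positions[i, ])
      v <- pmin(pmax(v, -span), span)   # clamp velocity to the box span
      x <- pmin(pmax(positions[i, ] + v, space$lower), space$upper)
      cost <- objective(x)
      if (!is.finite(cost))
        stop("objective returned a non-finite cost; optimization aborted")
      n_evals <- n_evals + 1L
      velocities[i, ] <- v
      positions[i, ] <- x
      costs[i] <- cost
      if (cost < pbest_cost[i]) {
        pbest_cost[i] <- cost
        pbest_pos[i, ] <- x
      }
      if (cost < best_cost) {
        best_cost <- cost
        best_position <- x
      }
    }
    w <- w * config$damping
    trace[t] <- best_cost
  }
  new_optimization_result(best_position, best_cost, trace, n_evals, "pso")
}

#' Dispatch an optimizer by configuration class
#'
#' @param objective Objective function (smaller is better).
#' @param space A [search_space()].
#' @param config An `ajs_config`, `ga_config` or `pso_config`.
#' @return An `optimization_result`.
#' @export
run_optimizer <- function(objective, space, config) {
  if (inherits(config, "ajs_config")) ajs_optimize(objective, space, config)
  else if (inherits(config, "ga_config")) ga_optimize(objective, space, config)
  else if (inherits(config, "pso_config")) pso_optimize(objective, space, config)
  else stop("unrecognized optimizer configuration")
}
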