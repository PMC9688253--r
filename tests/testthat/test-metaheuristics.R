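test_that("ocean current points from the attenuated swarm mean to the best", {
  pos <- rbind(c(1, -1), c(-1, 1))            # zero column means
  expect_equal(ocean_current(pos, c(1, 1), phi = 3, draw = fixed_draw(0.7)),
               c(1, 1))
  pos2 <- rbind(c(1, 1), c(0, 0))             # means (0.5, 0.5)
  expect_equal(ocean_current(pos2, c(1, 1), phi = 3, draw = fixed_draw(0.2)),
               c(0.7, 0.7))
  # best exactly at phi*u*mean cancels to the zero vector
  expect_equal(ocean_current(pos2, c(0.3, 0.3), phi = 3,
                             draw = fixed_draw(0.2)),
               c(0, 0))
  expect_error(ocean_current(matrix(numeric(0), 0, 2), c(1, 1), 3),
               "non-empty")
})

test_that("drift and passive steps follow their update rules", {
  expect_equal(drift_step(c(0, 0), c(1, 2), draw = fixed_draw(0.5)),
               c(0.5, 1.0))
  expect_equal(drift_step(c(1, 1), c(0, 0), draw = fixed_draw(0.9)),
               c(1, 1))
  expect_equal(drift_step(c(0, 0), c(1, 2), draw = fixed_draw(1)), c(1, 2))
  expect_error(drift_step(c(0, 0), c(1, 2, 3)), "length")

  sp <- search_space(1, 0, 1)
  expect_equal(passive_step(0.5, sp, omega = 0.1, draw = fixed_draw(0.5)),
               0.55)
  expect_equal(passive_step(0.5, sp, omega = 0, draw = fixed_draw(0.9)), 0.5)
  # passive motion may exit the box; wrapping restores feasibility
  out <- passive_step(0.99, sp, omega = 0.5, draw = fixed_draw(0.9))
  expect_gt(out, 1)
  expect_true(wrap_bounds(out, sp) >= 0 && wrap_bounds(out, sp) <= 1)
})

test_that("active motion moves toward the lower-cost partner, ties toward j", {
  expect_equal(active_step(c(0, 0), c(1, 0), cost_i = 5, cost_j = 1,
                           draw = fixed_draw(1)), c(1, 0))
  expect_equal(active_step(c(0, 0), c(1, 0), cost_i = 1, cost_j = 5,
                           draw = fixed_draw(1)), c(-1, 0))
  # equal costs take the ">=" branch: toward j
  expect_equal(active_step(c(0, 0), c(1, 0), cost_i = 2, cost_j = 2,
                           draw = fixed_draw(0.5)), c(0.5, 0))
  expect_equal(active_step(c(2, 3), c(2, 3), 1, 9, draw = fixed_draw(0.8)),
               c(2, 3))
})

test_that("time control decays with iteration and stays in [0, 1)", {
  expect_equal(time_control(25, 50, draw = fixed_draw(0.75)), 0.25)
  expect_equal(time_control(50, 50, draw = fixed_draw(0.9)), 0)
  expect_equal(time_control(3, 50, draw = fixed_draw(0.5)), 0)
  expect_error(time_control(0, 50), "out of range")
  expect_error(time_control(51, 50), "out of range")
  for (t in c(1, 10, 37, 50)) {
    for (u in c(0, 0.21, 0.5, 0.99)) {
      v <- time_control(t, 50, draw = fixed_draw(u))
      expect_gte(v, 0)
      expect_lt(v, 1)
    }
  }
})

test_that("wrap_bounds reflects to the opposite bound, repeatedly if needed", {
  sp <- search_space(1, 0, 1)
  expect_equal(wrap_bounds(0.5, sp), 0.5)
  expect_equal(wrap_bounds(1.2, sp), 0.2)
  expect_equal(wrap_bounds(-0.3, sp), 0.7)
  expect_equal(wrap_bounds(2.5, sp), 0.5)    # two wraps
  sp2 <- search_space(2, c(-1, 0), c(1, 2))
  expect_equal(wrap_bounds(c(1.5, -0.5), sp2), c(-0.5, 1.5))
  expect_error(wrap_bounds(c(NaN, 0), sp2), "non-finite")
})

test_that("optimizers handle constant and quadratic objectives", {
  sp <- search_space(1, 0, 1)
  for (cfg in list(ajs_config(seed = 5), ga_config(seed = 5),
                   pso_config(seed = 5))) {
    res <- run_optimizer(function(x) 7, sp, cfg)
    expect_equal(res$best_cost, 7)
    expect_true(all(res$trace == 7))
    res2 <- run_optimizer(quadratic_1d, sp, cfg)
    expect_lt(abs(res2$best_position - 0.25), 0.1)
  }
})

test_that("best-so-far traces are monotone and positions feasible", {
  sp <- search_space(3, -1, 1)
  for (seed in 1:3) {
    for (cfg in list(ajs_config(seed = seed), ga_config(seed = seed),
                     pso_config(seed = seed))) {
      res <- run_optimizer(sphere, sp, cfg)
      expect_true(all(diff(res$trace) <= 0))
      expect_equal(res$best_cost, res$trace[length(res$trace)])
      expect_true(all(res$best_position >= -1 & res$best_position <= 1))
      expect_equal(res$best_cost, sphere(res$best_position))
    }
  }
})

test_that("a fixed seed reproduces optimizer runs exactly", {
  sp <- search_space(2, -1, 1)
  for (make in list(ajs_config, ga_config, pso_config)) {
    a <- run_optimizer(sphere, sp, make(seed = 11))
    b <- run_optimizer(sphere, sp, make(seed = 11))
    expect_identical(a, b)
    c <- run_optimizer(sphere, sp, make(seed = 12))
    expect_false(identical(a$best_position, c$best_position))
  }
})

test_that("config constructors validate their invariants", {
  expect_error(ajs_config(pop_size = 1), "pop_size")
  expect_error(ajs_config(c0 = 1), "c0")
  expect_error(ajs_config(phi = 0), "phi")
  expect_error(ga_config(elitism = 10, pop_size = 10), "elitism")
  expect_error(pso_config(damping = 1.5), "damping")
  expect_error(search_space(2, lower = c(0, 1), upper = c(1, 1)),
               "strictly below")
})

test_that("non-finite objective values abort with a diagnostic", {
  sp <- search_space(1, 0, 1)
  bad <- function(x) if (x > 0.5) NaN else x
  expect_error(ajs_optimize(bad, sp, ajs_config(seed = 2)), "non-finite")
})

test_that("convergence traces round-trip through CSV", {
  sp <- search_space(2, -1, 1)
  res <- ajs_optimize(sphere, sp, ajs_config(seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(res, path)
  df <- read.csv(path)
  expect_equal(df$best_cost, res$trace)
  expect_equal(df$iteration, seq_along(res$trace))
})
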