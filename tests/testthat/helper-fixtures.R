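# Shared fixtures, all built in code.

# Fixed-value "uniform" sources for hand-checking the stochastic operators.
fixed_draw <- function(value) function(n) rep(value, n)

# Two well-separated Gaussian classes over small blocks: near-zero Bayes
# error, used to pin down the MSE cost and metric ceilings.
make_separable_dataset <- function(n = 120, d = c(5L, 5L), sep = 6,
                                   seed = 42L) {
  withr::with_seed(seed, {
    labels <- rep(c("a", "b"), length.out = n)
    shift <- ifelse(labels == "a", -sep / 2, sep / 2)
    blocks <- lapply(seq_along(d), function(b) {
      m <- matrix(stats::rnorm(n * d[b]), nrow = n)
      m[, 1L] <- m[, 1L] + shift   # one strongly separating column per block
      feature_block(sprintf("sep%d", b), m)
    })
    multiview_dataset(blocks, labels)
  })
}

# Brute-force grid argmin for 1-D objectives on [lo, hi].
grid_optimum <- function(f, lo = 0, hi = 1, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  grid[which.min(vapply(grid, f, numeric(1L)))]
}

quadratic_1d <- function(x) (x - 0.25)^2
sphere <- function(x) sum(x^2)

# Learned block weights even when the ranked selection degenerates.
mowfs_weights <- function(dataset, spec, config, cost_seed) {
  fit <- tryCatch(mowfs(dataset, spec, config, cost_seed = cost_seed),
                  degenerate_selection_error = function(e) list(weights = e$weights))
  fit$weights$weights
}

fowfs_weights <- function(dataset, spec, config, cost_seed) {
  fit <- tryCatch(fowfs(dataset, spec, config, cost_seed = cost_seed),
                  degenerate_selection_error = function(e) list(weights = e$weights))
  fit$weights$weights
}
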