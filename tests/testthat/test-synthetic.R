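test_that("generated blocks match the configured widths and masks", {
  sim <- generate_dataset(synth_config(n_samples = 80, n_classes = 3,
                                       block_dims = c(12L, 20L, 8L),
                                       informative_frac = c(0.5, 0.25, 0),
                                       effect_size = 2, seed = 9))
  expect_equal(block_dims(sim$dataset), c(12L, 20L, 8L))
  expect_equal(sim$dataset$n_samples, 80L)
  expect_length(sim$truth$informative_mask, 40L)
  # informative counts are exact per block: round(frac * d)
  per_block <- split(sim$truth$informative_mask,
                     rep(1:3, c(12L, 20L, 8L)))
  expect_equal(vapply(per_block, sum, integer(1L), USE.NAMES = FALSE),
               c(6L, 5L, 0L))
  expect_equal(sim$truth$block_quality, c(1, 0.5, 0))
})

test_that("identical configs and seeds give identical datasets", {
  cfg <- synth_config(n_samples = 50, n_classes = 4,
                      block_dims = c(6L, 6L), seed = 13)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$dataset$blocks[[1]]$matrix, b$dataset$blocks[[1]]$matrix)
  expect_identical(a$dataset$labels, b$dataset$labels)
  c <- generate_dataset(synth_config(n_samples = 50, n_classes = 4,
                                     block_dims = c(6L, 6L), seed = 14))
  expect_false(identical(a$dataset$blocks[[1]]$matrix,
                         c$dataset$blocks[[1]]$matrix))
})

test_that("noise columns look standard normal", {
  sim <- generate_dataset(synth_config(n_samples = 400, n_classes = 2,
                                       block_dims = c(30L),
                                       informative_frac = 0.2,
                                       effect_size = 2,
                                       class_proportions = c(0.5, 0.5),
                                       seed = 5))
  noise <- sim$dataset$blocks[[1]]$matrix[, !sim$truth$informative_mask]
  mus <- colMeans(noise)
  expect_true(all(abs(mus) < 3 / sqrt(400)))
  expect_true(all(abs(apply(noise, 2, sd) - 1) < 0.2))
})

test_that("zero effect size yields majority-rate accuracy", {
  withr::with_seed(31, seeds <- sample.int(1e6, 3))
  accs <- vapply(seeds, function(s) {
    sim <- generate_dataset(synth_config(n_samples = 250, n_classes = 3,
                                         block_dims = c(10L, 10L),
                                         informative_frac = 0.5,
                                         effect_size = 0, seed = s))
    train_eval(concat_blocks(sim$dataset), sim$dataset$labels,
               classifier_spec("svm"), seed = s)$accuracy
  }, numeric(1L))
  base <- 0.65   # dominant class proportion
  expect_lt(abs(mean(accs) - base), 0.12)
})

test_that("strong effects push fused accuracy above 0.95", {
  withr::with_seed(32, seeds <- sample.int(1e6, 10))
  accs <- vapply(seeds, function(s) {
    sim <- generate_dataset(synth_config(n_samples = 300, n_classes = 7,
                                         block_dims = c(20L, 20L, 20L),
                                         informative_frac = 0.5,
                                         effect_size = 3, seed = s))
    train_eval(concat_blocks(sim$dataset), sim$dataset$labels,
               classifier_spec("svm"), seed = s)$accuracy
  }, numeric(1L))
  expect_gt(median(accs), 0.95)
})

test_that("the two-block probe orders blocks by quality", {
  probe <- make_two_block_probe(seed = 8)
  expect_equal(block_dims(probe$dataset), c(20L, 20L))
  expect_equal(probe$dataset$n_classes, 2L)
  expect_gt(probe$truth$block_quality[1], probe$truth$block_quality[2])
  expect_equal(sum(probe$truth$informative_mask), 20L)
  expect_identical(make_two_block_probe(seed = 8)$dataset$blocks[[2]]$matrix,
                   probe$dataset$blocks[[2]]$matrix)

  accs <- vapply(1:2, function(b) {
    sub <- multiview_dataset(list(probe$dataset$blocks[[b]]),
                             probe$dataset$labels)
    train_eval(concat_blocks(sub), sub$labels, classifier_spec("svm"),
               seed = 8)$accuracy
  }, numeric(1L))
  expect_gt(accs[1], accs[2])
})

test_that("feature tables round-trip through CSV", {
  sim <- generate_dataset(synth_config(n_samples = 30, n_classes = 2,
                                       block_dims = c(4L, 3L), seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(sim$dataset, path)
  back <- read_feature_table(path)
  expect_equal(block_dims(back), c(4L, 3L))
  expect_equal(back$labels, sim$dataset$labels)
  expect_equal(back$blocks[[2]]$matrix, sim$dataset$blocks[[2]]$matrix,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("degenerate configurations are rejected", {
  expect_error(synth_config(informative_frac = 1.5), "informative_frac")
  expect_error(synth_config(class_proportions = c(0.5, 0.4), n_classes = 2),
               "sum")
  expect_error(generate_dataset(synth_config(n_samples = 8, n_classes = 7)),
               "too small")
})
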