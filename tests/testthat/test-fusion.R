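test_that("concatenation stacks blocks in order and keeps provenance", {
  b1 <- feature_block("x", matrix(1:4, 2))
  b2 <- feature_block("y", matrix(5:8, 2))
  ds <- multiview_dataset(list(b1, b2), c("a", "b"))
  fused <- concat_blocks(ds)
  expect_equal(dim(fused$matrix), c(2L, 4L))
  expect_equal(fused$matrix[, 1:2], b1$matrix)
  expect_equal(fused$matrix[, 3:4], b2$matrix)
  expect_equal(fused$strategy, "CFS")
  expect_equal(fused$provenance$extractor_id, c("x", "x", "y", "y"))
  expect_equal(fused$provenance$column, c(1L, 2L, 1L, 2L))

  single <- concat_blocks(multiview_dataset(list(b1), c("a", "b")))
  expect_identical(single$matrix, b1$matrix)
})

test_that("fused width is the sum of block widths at the published sizes", {
  blocks <- lapply(c(vgg16 = 512L, effb0 = 1024L, resnet50 = 1024L),
                   function(d) feature_block("b", matrix(0, 2, d)))
  ds <- multiview_dataset(blocks, c("a", "b"))
  expect_equal(ncol(concat_blocks(ds)$matrix), 2560L)
  expect_equal(fusion_space(ds, "feature")$dim, 2560L)
  expect_equal(fusion_space(ds, "model")$dim, 3L)
})

test_that("model-level weights scale whole blocks", {
  blocks <- Map(function(id, v) feature_block(id, matrix(v, 2, 1)),
                c("p", "q", "r"), c(2, 4, 6))
  ds <- multiview_dataset(unname(blocks), c("a", "b"))
  w <- weight_scheme("model", c(0.5, 0.25, 1))
  fused <- apply_model_weights(ds, w)
  expect_equal(fused$matrix[1, ], c(1, 1, 6))

  ones <- apply_model_weights(ds, weight_scheme("model", c(1, 1, 1)))
  expect_identical(ones$matrix, concat_blocks(ds)$matrix)

  zero_first <- apply_model_weights(ds, weight_scheme("model", c(0, 1, 1)))
  expect_true(all(zero_first$matrix[, 1] == 0))
  expect_error(apply_model_weights(ds, weight_scheme("model", c(1, 1))),
               "one weight per block")
  expect_error(weight_scheme("model", c(0.5, 1.2, 0)), "\\[0, 1\\]")
})

test_that("feature-level weights scale single columns", {
  blocks <- Map(function(id, v) feature_block(id, matrix(v, 2, 1)),
                c("p", "q", "r"), c(2, 4, 6))
  ds <- multiview_dataset(unname(blocks), c("a", "b"))
  fused <- apply_feature_weights(ds, weight_scheme("feature", c(0.5, 0.5, 0.5)))
  expect_equal(fused$matrix[1, ], c(1, 2, 3))

  ones <- apply_feature_weights(ds, weight_scheme("feature", rep(1, 3)))
  expect_identical(ones$matrix, concat_blocks(ds)$matrix)

  one_zero <- apply_feature_weights(ds, weight_scheme("feature", c(1, 0, 1)))
  expect_equal(sum(colSums(one_zero$matrix == 0) == 2), 1L)
  expect_error(apply_feature_weights(ds, weight_scheme("feature", c(1, 1))),
               "need 3 weights")
})

test_that("ranked selection is strict at the 0.5 boundary", {
  m <- select_ranked(weight_scheme("feature", c(0.6, 0.2, 0.9)))
  expect_equal(m$keep, c(TRUE, FALSE, TRUE))
  expect_error(select_ranked(weight_scheme("feature", c(0.5))),
               class = "degenerate_selection_error")
  expect_error(select_ranked(weight_scheme("feature", c(0.4, 0.3))),
               class = "degenerate_selection_error")
  # selection at a custom threshold stays strict
  m2 <- select_ranked(weight_scheme("feature", c(0.3, 0.31)), threshold = 0.3)
  expect_equal(m2$keep, c(FALSE, TRUE))
})

test_that("model-level masks expand to block-width column flags", {
  blocks <- list(feature_block("p", matrix(0, 2, 2)),
                 feature_block("q", matrix(1, 2, 3)))
  ds <- multiview_dataset(blocks, c("a", "b"))
  mask <- select_ranked(weight_scheme("model", c(0.9, 0.1)))
  keep <- expand_mask(mask, ds)
  expect_equal(keep, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  reduced <- mask_columns(concat_blocks(ds), keep)
  expect_equal(ncol(reduced$matrix), 2L)
  expect_equal(unique(reduced$provenance$extractor_id), "p")
})

test_that("the MSE cost is near zero on separable data and deterministic", {
  ds <- make_separable_dataset()
  spec <- classifier_spec("svm")
  ones <- weight_scheme("model", c(1, 1))
  cost1 <- mse_cost(ones, ds, spec, seed = 3)
  expect_lt(cost1, 0.05)
  expect_identical(cost1, mse_cost(ones, ds, spec, seed = 3))
  # annihilating every feature can only hurt
  cost0 <- mse_cost(weight_scheme("model", c(0, 0)), ds, spec, seed = 3)
  expect_gte(cost0, cost1)
})

test_that("cost evaluations do not perturb the caller's RNG stream", {
  ds <- make_separable_dataset(n = 60)
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(mse_cost(weight_scheme("model", c(1, 1)), ds,
                     classifier_spec("svm"), seed = 1))
  expect_identical(runif(1), before)
})

test_that("AWFS weights track standalone block accuracy, best block at 1", {
  probe <- make_two_block_probe(seed = 4)
  aw <- awfs(probe$dataset, classifier_spec("svm"), seed = 4)
  expect_equal(max(aw$weights$weights), 1)
  expect_equal(which.max(aw$weights$weights), 1L)  # informative block first
  expect_true(all(aw$weights$weights > 0 & aw$weights$weights <= 1))
  expect_equal(aw$fused$strategy, "AWFS")

  # symmetry: identical blocks get identical weights
  b <- feature_block("z", matrix(rnorm(40), 20))
  labs <- rep(c("a", "b"), 10)
  same <- multiview_dataset(list(b, b, b), labs)
  aw2 <- awfs(same, classifier_spec("dt"), seed = 1)
  expect_equal(aw2$weights$weights, c(1, 1, 1))
})

test_that("MOWFS returns in-range weights and a block-shaped ranked set", {
  probe <- make_two_block_probe(seed = 3)
  fit <- tryCatch(
    mowfs(probe$dataset, classifier_spec("svm"),
          ajs_config(max_iter = 10, seed = 3), cost_seed = 3),
    degenerate_selection_error = function(e) list(weights = e$weights))
  expect_true(all(fit$weights$weights >= 0 & fit$weights$weights <= 1))
  expect_length(fit$weights$weights, 2L)
  if (!is.null(fit$mask)) {
    kept_ids <- unique(fit$fused$provenance$extractor_id)
    expect_equal(sort(kept_ids),
                 sort(c("block1", "block2")[fit$mask$keep]))
  }
})

test_that("FOWFS optimizes one weight per fused column", {
  probe <- make_two_block_probe(seed = 5)
  fit <- tryCatch(
    fowfs(probe$dataset, classifier_spec("svm"),
          ajs_config(max_iter = 5, seed = 5), cost_seed = 5),
    degenerate_selection_error = function(e) list(weights = e$weights))
  expect_length(fit$weights$weights, 40L)
  expect_true(all(fit$weights$weights >= 0 & fit$weights$weights <= 1))
  if (!is.null(fit$mask))
    expect_equal(ncol(fit$fused$matrix), sum(fit$mask$keep))
})

test_that("MOWFS runs are reproducible end-to-end under a fixed seed", {
  probe <- make_two_block_probe(seed = 6)
  cfg <- ajs_config(max_iter = 5, seed = 6)
  w1 <- mowfs_weights(probe$dataset, classifier_spec("svm"), cfg, cost_seed = 6)
  w2 <- mowfs_weights(probe$dataset, classifier_spec("svm"), cfg, cost_seed = 6)
  expect_identical(w1, w2)
})

test_that("weights tables carry provenance and selection flags", {
  probe <- make_two_block_probe(seed = 1)
  w <- weight_scheme("model", c(0.8, 0.2))
  mask <- select_ranked(w)
  df <- weights_table(w, probe$dataset, mask)
  expect_equal(nrow(df), 2L)
  expect_equal(df$selected, c(TRUE, FALSE))
  wf <- weight_scheme("feature", rep(0.6, 40))
  df2 <- weights_table(wf, probe$dataset)
  expect_equal(nrow(df2), 40L)
  expect_equal(table(df2$extractor_id)[["block1"]], 20L)
})
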