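test_that("AUC equals the concordant-pair probability with tie handling", {
  expect_equal(roc_auc(c(1, 0), c(0.9, 0.1)), 1)
  expect_equal(roc_auc(c(1, 0), c(0.5, 0.5)), 0.5)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2)), 0.75)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("AUC matches brute-force pair counting on random weighted data", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    scores <- round(runif(n), sample(c(1, 2, 7), 1))  # coarse rounding forces ties
    weights <- runif(n, 0.2, 2)
    expect_equal(roc_auc(labels, scores, weights),
                 brute_auc(labels, scores, weights), tolerance = 1e-12)
  }
})

test_that("TSS is sensitivity + specificity - 1", {
  expect_equal(tss(1, 1), 1)
  expect_equal(tss(0.5, 0.5), 0)
  # at the published optimum (sens 80.1%, spec 85.5%) the skill is 0.656
  expect_equal(tss(0.801, 0.855), 0.656)
})

test_that("confusion at a threshold is presence-inclusive and weighted", {
  labels <- c(1, 0, 1, 0); scores <- c(0.9, 0.6, 0.4, 0.1)
  cf <- confusion_at(labels, scores, NULL, 0.5)
  expect_equal(cf[c("tp", "fp", "fn", "tn")],
               tibble::tibble(tp = 1, fp = 1, fn = 1, tn = 1))
  expect_equal(cf$pcc, 0.5)
  expect_equal(confusion_at(labels, scores, NULL, 0)$sensitivity, 1)
  expect_equal(confusion_at(labels, scores, NULL, 0.91)$specificity, 1)
  expect_equal(confusion_at(labels, scores, NULL, 0.91)$sensitivity, 0)
  # a score exactly at the threshold classifies as presence
  expect_equal(confusion_at(labels, scores, NULL, 0.9)$tp, 1)
})

test_that("optimal threshold maximises TSS with accuracy then lower-t ties", {
  # hand-enumerated: optimum sum 1.5 attained at several candidates; the
  # lowest (0.25, the first midpoint) wins the tie
  got <- optimal_threshold(c(1, 0, 1, 0), c(0.9, 0.6, 0.4, 0.1))
  expect_equal(got$threshold, 0.25)
  expect_equal(got$tss, 0.5)
  # perfectly separated scores: lowest midpoint in the gap, sens = spec = 1
  sep <- optimal_threshold(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(sep[c("sensitivity", "specificity")],
               tibble::tibble(sensitivity = 1, specificity = 1))
  expect_equal(sep$threshold, 0.5)
  # halving the weights of a duplicated point leaves the optimum unchanged
  l <- c(1, 0, 1, 0); s <- c(0.9, 0.6, 0.4, 0.1)
  dup <- optimal_threshold(c(l, 1), c(s, 0.9), c(0.5, 1, 1, 1, 0.5))
  expect_equal(dup$threshold, got$threshold)
})

test_that("optimal threshold agrees with exhaustive search on random data", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), sample(c(1, 3), 1))
    weights <- runif(n, 0.2, 2)
    got <- optimal_threshold(labels, scores, weights)
    want <- brute_optimal_threshold(labels, scores, weights)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$tss, want$tss, tolerance = 1e-12)
  }
})

test_that("spatial blocks tile the extent and balance folds", {
  sp <- grid_spec(80, 160, 0, 0, 25)     # 4000 x 2000 km
  pts <- tibble::tibble(x = runif(50, 0, 3999), y = runif(50, 0, 1999))
  fa <- make_spatial_blocks(sp, pts, block_km = 2000, k = 2, rng_seed = 1)
  expect_equal(nrow(fa$blocks), 2)
  expect_setequal(fa$blocks$fold, c(1, 2))
  # 10 blocks over 5 folds: exactly two blocks per fold
  sp10 <- grid_spec(80, 200, 0, 0, 25)   # 5000 x 2000 km -> 5 x 2 blocks of 1000
  pts10 <- tibble::tibble(x = runif(400, 0, 4999), y = runif(400, 0, 1999))
  fa10 <- make_spatial_blocks(sp10, pts10, block_km = 1000, k = 5, rng_seed = 2)
  expect_equal(nrow(fa10$blocks), 10)
  expect_true(all(table(fa10$blocks$fold) == 2))
  # a point on a block's lower-left corner belongs to that block
  corner <- make_spatial_blocks(sp, tibble::tibble(x = c(2000, 10), y = c(0, 10)),
                                block_km = 2000, k = 2, rng_seed = 1)
  right_block <- corner$blocks$block_id[corner$blocks$bx == 1]
  expect_equal(corner$points$block_id[1], right_block)
  expect_error(make_spatial_blocks(sp, tibble::tibble(x = 10, y = 10),
                                   block_km = 2000, k = 2, rng_seed = 1),
               "no points")
})

test_that("block CV keeps train and test spatially disjoint and scores folds", {
  frame <- null_frame(240, seed = 3)
  fa <- make_spatial_blocks(grid_spec(60, 60, 0, 0, 5), frame,
                            block_km = 60, k = 4, rng_seed = 3)
  res <- suppressWarnings(block_cv(frame, list(learner_spec("GLM")), fa))
  expect_equal(sort(unique(res$runs$replicate)), sort(unique(fa$points$fold)))
  for (f in unique(fa$points$fold)) {
    train_blocks <- unique(fa$points$block_id[fa$points$fold != f])
    test_blocks <- unique(fa$points$block_id[fa$points$fold == f])
    expect_length(intersect(train_blocks, test_blocks), 0)
  }
})

test_that("prediction rasters are compared by Pearson correlation", {
  sp <- grid_spec(2, 2, 0, 0, 5)
  a <- grid_raster(sp, matrix(c(0, 1, 2, 3), 2, 2))
  expect_equal(compare_predictions_pearson(a, a), 1)
  b <- grid_raster(sp, -a$values + 1)
  expect_equal(compare_predictions_pearson(a, b), -1)
  d <- grid_raster(sp, matrix(c(0, 1, 2, 4), 2, 2))
  expect_equal(compare_predictions_pearson(a, d), cor(c(0, 1, 2, 3), c(0, 1, 2, 4)))
  expect_equal(compare_predictions_pearson(a, d), 0.9827076, tolerance = 1e-6)
  flat <- grid_raster(sp, matrix(1, 2, 2))
  expect_error(compare_predictions_pearson(a, flat), "variance")
})
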