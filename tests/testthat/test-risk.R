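toy_spec <- grid_spec(2, 2, 0, 0, 5)

test_that("binarisation is presence-inclusive at the threshold", {
  r <- grid_raster(toy_spec, matrix(c(0.38, 0.389, 0.40, 0.2), 2, 2, byrow = TRUE))
  b <- binarize(r, 0.389)
  expect_equal(as.vector(t(b$values)), c(0, 1, 1, 0))
  expect_true(all(binarize(r, 0)$values == 1))
  expect_true(all(binarize(r, 1)$values == 0))     # all values < 1 here
  masked <- grid_raster(toy_spec, matrix(c(NA, 0.5, 0.5, 0.5), 2, 2))
  expect_true(binarize(masked, 0.4)$mask[1, 1])
})

test_that("population at risk sums suitable-cell population by zone", {
  pop <- grid_raster(toy_spec, matrix(c(10, 20, 30, 40), 2, 2, byrow = TRUE))
  bin <- binarize(grid_raster(toy_spec, matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE)), 0.5)
  one_zone <- grid_raster(toy_spec, matrix(1, 2, 2))
  rs <- population_at_risk(bin, pop, list(), one_zone)
  expect_equal(rs$overall$population_at_risk, 40)
  expect_equal(rs$zones$population_at_risk, 40)
  # all suitable: conservation of the total
  all1 <- binarize(grid_raster(toy_spec, matrix(1, 2, 2)), 0.5)
  expect_equal(population_at_risk(all1, pop, list(), one_zone)$overall$population_at_risk,
               100)
  # members identical to the point map: degenerate interval
  rs2 <- population_at_risk(bin, pop, list(bin, bin, bin), one_zone)
  expect_equal(rs2$overall$lower, 40)
  expect_equal(rs2$overall$upper, 40)
  # misalignment is an error
  pop_off <- grid_raster(grid_spec(2, 2, 1, 0, 5), matrix(1, 2, 2))
  expect_error(population_at_risk(bin, pop_off, list(), one_zone), "not aligned")
})

test_that("zone-wise population at risk partitions the overall total", {
  set.seed(6)
  sp <- grid_spec(8, 8, 0, 0, 5)
  pop <- grid_raster(sp, matrix(rpois(64, 50), 8, 8))
  suit <- grid_raster(sp, matrix(runif(64), 8, 8))
  zones <- grid_raster(sp, matrix(sample(1:4, 64, TRUE), 8, 8))
  bin <- binarize(suit, 0.4)
  rs <- population_at_risk(bin, pop, list(), zones)
  expect_identical(sum(rs$zones$population_at_risk),
                   rs$overall$population_at_risk)   # exact for integer counts
  expect_equal(tidy(rs), rs$zones)
  expect_equal(glance(rs), rs$overall)
})

test_that("binary overlap partitions the population into four classes", {
  pop <- grid_raster(toy_spec, matrix(c(1, 2, 4, 8), 2, 2, byrow = TRUE))
  a <- binarize(grid_raster(toy_spec, matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE)), 0.5)
  b <- binarize(grid_raster(toy_spec, matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE)), 0.5)
  ov <- overlap_binary(a, b, pop)
  got <- setNames(ov$table$population, ov$table$class)
  expect_equal(got, c(neither = 8, a_only = 2, b_only = 4, both = 1))
  expect_equal(sum(ov$table$population), sum(raster_values(pop)))
  # a == b: no single-disease classes
  same <- overlap_binary(a, a, pop)
  expect_equal(same$table$population[same$table$class %in% c("a_only", "b_only")],
               c(0, 0))
  # disjoint maps: no co-suitable population
  compl <- binarize(grid_raster(toy_spec, 1 - a$values), 0.5)
  expect_equal(overlap_binary(a, compl, pop)$table$population[4], 0)
})

test_that("IU classification applies the any-suitable-cell default rule", {
  sp <- grid_spec(2, 3, 0, 0, 5)
  bin <- binarize(grid_raster(sp, matrix(c(1, 1, 0, 0, 0, 1), 2, 3, byrow = TRUE)), 0.5)
  ius <- grid_raster(sp, matrix(c(1, 1, 2, 3, 3, 2), 2, 3, byrow = TRUE))
  mapped <- tibble::tibble(iu_index = 1:3, mapped = c(TRUE, FALSE, FALSE))
  tab <- classify_ius(bin, ius, mapped)
  expect_equal(tab$suitable, c(TRUE, TRUE, FALSE))   # IU3 has no suitable cell
  expect_equal(sum(tab$needs_mapping), 1)            # IU2 suitable, unmapped
  # min_fraction raises the bar: IU2 is 1/2 suitable, IU1 2/2
  strict <- classify_ius(bin, ius, mapped, min_fraction = 0.6)
  expect_equal(strict$suitable, c(TRUE, FALSE, FALSE))
  # matches the brute-force any-suitable-cell rule cell by cell
  brute <- vapply(1:3, function(i) {
    any(bin$values[ius$values == i] == 1, na.rm = TRUE)
  }, TRUE)
  expect_equal(tab$suitable, brute)
})

test_that("IUs without valid cells are flagged indeterminate", {
  sp <- grid_spec(2, 2, 0, 0, 5)
  bin <- binarize(grid_raster(sp, matrix(c(NA, NA, 1, 0), 2, 2, byrow = TRUE)), 0.5)
  ius <- grid_raster(sp, matrix(c(1, 1, 2, 2), 2, 2, byrow = TRUE))
  expect_message(tab <- classify_ius(bin, ius, tibble::tibble(iu_index = 1:2,
                                                              mapped = FALSE)),
                 "indeterminate")
  expect_true(tab$indeterminate[1])
  expect_false(tab$suitable[1] %in% TRUE)
})

test_that("share percentages reproduce reported rounding", {
  expect_equal(share_percentages(1311, 2870), 45.7)
  expect_equal(share_percentages(1655, 5712), 29.0)
  expect_equal(share_percentages(1, 3), 33.3)
  expect_equal(share_percentages(c(a = 1, b = 2), 8), c(a = 12.5, b = 25))
  expect_error(share_percentages(1, 0), "positive")
})

test_that("lowering the threshold never shrinks risk or suitable IUs", {
  set.seed(12)
  sp <- grid_spec(10, 10, 0, 0, 5)
  suit <- grid_raster(sp, matrix(runif(100), 10, 10))
  pop <- grid_raster(sp, matrix(rpois(100, 30), 10, 10))
  zones <- grid_raster(sp, matrix(1, 10, 10))
  ius <- grid_raster(sp, matrix(rep(1:10, each = 10), 10, 10))
  mapped <- tibble::tibble(iu_index = 1:10, mapped = FALSE)
  prev_risk <- -Inf; prev_ius <- -Inf
  for (t in seq(0.9, 0.1, by = -0.2)) {
    bin <- binarize(suit, t)
    risk <- population_at_risk(bin, pop, list(), zones)$overall$population_at_risk
    n_suit <- sum(classify_ius(bin, ius, mapped)$suitable)
    expect_gte(risk, prev_risk)
    expect_gte(n_suit, prev_ius)
    prev_risk <- risk; prev_ius <- n_suit
  }
})
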