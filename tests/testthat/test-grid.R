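test_that("grid specs validate and compare alignment field by field", {
  sp <- grid_spec(4, 3, x_min = 10, y_min = 20, cell_size = 5)
  expect_true(specs_aligned(sp, grid_spec(4, 3, 10, 20, 5)))
  expect_false(specs_aligned(sp, grid_spec(4, 3, 10, 20, 2.5)))
  expect_false(specs_aligned(sp, grid_spec(4, 3, 11, 20, 5)))
  expect_error(grid_spec(0, 3), "n_rows")
  expect_error(grid_spec(4, 3, cell_size = -1))
})

test_that("cell ownership follows the half-open right/top convention", {
  sp <- grid_spec(2, 2, 0, 0, 5)      # extent [0,10) x [0,10), row 1 north
  pc <- podomapr:::point_to_cell
  # interior points, manual index arithmetic
  expect_equal(pc(sp, 2.5, 7.5), list(row = 1L, col = 1L))
  expect_equal(pc(sp, 7.5, 2.5), list(row = 2L, col = 2L))
  # vertical shared edge x = 5 belongs to the right cell
  expect_equal(pc(sp, 5, 7.5)$col, 2L)
  # horizontal shared edge y = 5 belongs to the top cell (row 1)
  expect_equal(pc(sp, 2.5, 5)$row, 1L)
  # lower-left corner of the extent is inside; top and right edges are out
  expect_equal(pc(sp, 0, 0), list(row = 2L, col = 1L))
  expect_true(is.na(pc(sp, 10, 5)$col))
  expect_true(is.na(pc(sp, 5, 10)$row))
})

test_that("masked cells are excluded from raster statistics", {
  sp <- grid_spec(2, 2, 0, 0, 5)
  r <- grid_raster(sp, matrix(c(1, 2, 3, NA), 2, 2))
  expect_equal(sort(raster_values(r)), c(1, 2, 3))
  expect_true(r$mask[2, 2])
})

test_that("bilinear resampling interpolates and the identity holds", {
  sp <- grid_spec(2, 2, 0, 0, 5)
  src <- grid_raster(sp, matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE))
  # single target cell centred at the source centroid: symmetric average
  mid <- resample_to_grid(src, grid_spec(1, 1, 2.5, 2.5, 5), "bilinear")
  expect_equal(mid$values[1, 1], 0.5)
  # identical spec: identity
  same <- resample_to_grid(src, sp, "bilinear")
  expect_equal(same$values, src$values)
  # nearest-neighbour rule, checked by hand: target centre at (1,9) lies in
  # the top-left source cell (value 0)
  nn <- resample_to_grid(src, grid_spec(1, 1, 0, 8, 2), "nearest")
  expect_equal(nn$values[1, 1], 0)
  expect_error(resample_to_grid(src, grid_spec(2, 2, 100, 100, 5)), "overlap")
})

test_that("bilinear output lies within the hull of source neighbours", {
  set.seed(31)
  for (i in 1:20) {
    src <- grid_raster(grid_spec(6, 6, 0, 0, 5), matrix(runif(36), 6, 6))
    tgt <- grid_spec(5, 5, runif(1, 0, 4), runif(1, 0, 4), 4.4)
    out <- resample_to_grid(src, tgt, "bilinear")
    v <- raster_values(out)
    expect_true(all(v >= min(src$values) - 1e-12 & v <= max(src$values) + 1e-12))
  }
})

test_that("resampling masks cells touching nodata source neighbours", {
  sp <- grid_spec(3, 3, 0, 0, 5)
  vals <- matrix(1, 3, 3); vals[2, 2] <- NA
  src <- grid_raster(sp, vals)
  out <- resample_to_grid(src, grid_spec(3, 3, 1, 1, 4), "bilinear")
  expect_true(any(out$mask))
})

test_that("distance transform gives exact centre-to-centre distances", {
  sp <- grid_spec(3, 3, 0, 0, 5)
  fm <- grid_raster(sp, matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3))
  d <- distance_to_features(fm)
  expect_equal(d$values[2, 2], 0)                 # the feature cell itself
  expect_equal(d$values[1, 2], 5)                 # 4-neighbour, one 5-km step
  expect_equal(d$values[1, 1], 5 * sqrt(2), tolerance = 1e-12)  # diagonal
  expect_error(distance_to_features(grid_raster(sp, matrix(0, 3, 3))),
               "no feature")
})

test_that("distance transform equals brute-force all-pairs search", {
  set.seed(7)
  for (i in 1:5) {
    sp <- grid_spec(12, 15, 0, 0, 5)
    fm <- grid_raster(sp, matrix(rbinom(12 * 15, 1, 0.08), 12, 15))
    if (!any(fm$values == 1)) next
    expect_equal(distance_to_features(fm)$values, brute_distance(fm),
                 tolerance = 1e-10)
  }
})

test_that("point extraction returns cell values and flags invalid points", {
  sp <- grid_spec(2, 2, 0, 0, 5)
  vals <- matrix(c(7, 2, 3, 4), 2, 2, byrow = TRUE)
  stk <- covariate_stack(list(v = grid_raster(sp, vals)))
  got <- extract_at_points(stk, tibble::tibble(x = 2.5, y = 7.5))
  expect_equal(got$v, 7)                          # exact centre of cell (1,1)
  expect_warning(
    out <- extract_at_points(stk, tibble::tibble(x = c(2.5, 50), y = c(7.5, 50))),
    "outside")
  expect_equal(out$valid, c(TRUE, FALSE))
  expect_true(is.na(out$v[2]))
  expect_error(extract_at_points(stk, tibble::tibble(x = numeric(), y = numeric())),
               "no points")
  # boundary point: x = 5 owned by the right column
  on_edge <- extract_at_points(stk, tibble::tibble(x = 5, y = 7.5))
  expect_equal(on_edge$v, 2)
})

test_that("point extraction is translation-equivariant", {
  set.seed(13)
  vals <- matrix(runif(30), 5, 6)
  for (shift in list(c(3, -2), c(-10, 10))) {
    a <- covariate_stack(list(v = grid_raster(grid_spec(5, 6, 0, 0, 5), vals)))
    b <- covariate_stack(list(v = grid_raster(
      grid_spec(5, 6, shift[1], shift[2], 5), vals)))
    pts <- tibble::tibble(x = runif(20, 1, 29), y = runif(20, 1, 24))
    pts_b <- dplyr::mutate(pts, x = x + shift[1], y = y + shift[2])
    expect_equal(extract_at_points(a, pts)$v, extract_at_points(b, pts_b)$v)
  }
})

test_that("stack layers must align and stack validity is the intersection", {
  sp <- grid_spec(2, 2, 0, 0, 5)
  a <- grid_raster(sp, matrix(1, 2, 2))
  b <- grid_raster(sp, matrix(c(1, NA, 1, 1), 2, 2))
  expect_error(covariate_stack(list(a = a, b = grid_raster(grid_spec(2, 2, 1, 0, 5),
                                                           matrix(1, 2, 2)))),
               "not aligned")
  stk <- covariate_stack(list(a = a, b = b))
  expect_equal(sum(stack_valid_mask(stk)), 3)
})
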