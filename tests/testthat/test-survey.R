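survey_tbl <- function(...) {
  tibble::tibble(...)
}

test_that("exact-coordinate deduplication lets presence win conflicts", {
  rec <- survey_tbl(site_id = c("a", "b"), x = c(10, 10), y = c(5, 5),
                    cases = c(0L, 3L), country = "C01", source = "s")
  expect_message(out <- load_and_dedupe(rec), "collapsed 1")
  expect_equal(nrow(out), 1)
  expect_equal(out$cases, 3L)

  distinct <- survey_tbl(site_id = letters[1:5], x = 1:5, y = 1:5,
                         cases = 0L, country = "C01", source = "s")
  expect_equal(nrow(load_and_dedupe(distinct)), 5)

  # near-identical coordinates are NOT merged: dedup is exact, no tolerance
  near <- survey_tbl(site_id = c("a", "b"), x = c(10, 10), y = c(5, 5.0000001),
                     cases = 0L, country = "C01", source = "s")
  expect_equal(nrow(load_and_dedupe(near)), 2)
})

test_that("survey loading validates its contract", {
  expect_error(load_and_dedupe(survey_tbl(x = 1, y = 2)), "lacks column")
  bad <- survey_tbl(site_id = "a", x = NA_real_, y = 2, cases = 1L,
                    country = "C", source = "s")
  expect_error(load_and_dedupe(bad), "numeric and non-missing")
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(survey_tbl(site_id = "a", x = 1, y = 2, cases = 2L,
                       country = "C", source = "s"), f, row.names = FALSE)
  expect_equal(load_and_dedupe(f)$cases, 2L)
})

test_that("endemicity labels are 1 iff cases reported; all weights 1", {
  rec <- survey_tbl(site_id = c("a", "b"), x = 1:2, y = 1:2, cases = c(3L, 0L),
                    country = "C", source = "s")
  lab <- label_endemicity(rec)
  expect_equal(lab$label, c(1L, 0L))
  expect_equal(lab$weight, c(1, 1))
  expect_equal(nrow(label_endemicity(rec[0, ])), 0)
})

test_that("evidence rescaling maps the most negative score to 1", {
  ev <- tibble::tibble(country = c("A", "B"), score = c(-4, -1))
  w <- rescale_evidence(ev, floor = 0.25)
  expect_equal(w$weight[w$country == "A"], 1)
  expect_equal(w$weight[w$country == "B"], 0.25)
  # single eligible country: degenerate rescale
  expect_equal(rescale_evidence(tibble::tibble(country = "A", score = -2))$weight, 1)
  # non-negative scores are ineligible
  mixed <- rescale_evidence(tibble::tibble(country = c("A", "B"), score = c(-2, 3)))
  expect_equal(mixed$country, "A")
  expect_error(rescale_evidence(tibble::tibble(country = "B", score = 3)),
               "below 0")
})

test_that("pseudo-absence sampling is uniform, weighted and reproducible", {
  sp <- grid_spec(4, 5, 0, 0, 5)
  zones <- grid_raster(sp, matrix(rep(c(1, 2), each = 10), 4, 5))
  w <- tibble::tibble(country = c("A", "B"), country_index = 1:2,
                      weight = c(1, 0.4))
  pts <- sample_pseudo_absences(zones, w, n = 100, rng_seed = 3)
  expect_equal(nrow(pts), 100)
  expect_true(all(pts$label == 0L))
  expect_true(all(pts$origin == "pseudo_absence"))
  expect_true(all(pts$weight %in% c(1, 0.4)))
  expect_equal(pts$weight == 1, pts$country == "A")
  expect_identical(pts, sample_pseudo_absences(zones, w, n = 100, rng_seed = 3))
  # degenerate support: a single eligible cell absorbs every draw
  one <- grid_raster(sp, matrix(1, 4, 5),
                     mask = matrix(c(FALSE, rep(TRUE, 19)), 4, 5))
  pts1 <- sample_pseudo_absences(one, w, n = 10, rng_seed = 1)
  expect_equal(nrow(unique(pts1[c("x", "y")])), 1)
  masked <- grid_raster(sp, matrix(9, 4, 5))
  expect_error(sample_pseudo_absences(masked, w, 5, 1), "no eligible")
})

test_that("pseudo-absence placement is uniform over eligible cells", {
  sp <- grid_spec(4, 5, 0, 0, 5)
  zones <- grid_raster(sp, matrix(1, 4, 5))
  w <- tibble::tibble(country = "A", country_index = 1, weight = 1)
  pts <- sample_pseudo_absences(zones, w, n = 10000, rng_seed = 9)
  counts <- table(paste(pts$x, pts$y))
  expect_equal(length(counts), 20)
  gof <- chisq.test(as.numeric(counts))
  expect_gt(gof$p.value, 0.01)
})

test_that("model frame assembly extracts, drops and validates", {
  sp <- grid_spec(2, 2, 0, 0, 5)
  stk <- covariate_stack(list(v = grid_raster(sp, matrix(1:4, 2, 2))))
  pres <- survey_tbl(site_id = c("p1", "p2", "p3"), x = c(2, 7, 2),
                     y = c(2, 2, 7), cases = 1L, country = "C", source = "s")
  abs_ <- survey_tbl(site_id = c("a1", "a2", "a3"), x = c(7, 2.1, 7.2),
                     y = c(7, 2.2, 7.3), cases = 0L, country = "C", source = "s")
  lab <- label_endemicity(dplyr::bind_rows(pres, abs_))
  frame <- build_model_frame(lab, NULL, stk)
  expect_equal(nrow(frame), 6)
  expect_setequal(attr(frame, "covariates"), "v")
  # one point off-grid: dropped and counted
  lab_off <- dplyr::bind_rows(lab, label_endemicity(
    survey_tbl(site_id = "far", x = 99, y = 99, cases = 1L, country = "C",
               source = "s")))
  expect_message(f2 <- build_model_frame(lab_off, NULL, stk), "dropped 1")
  expect_equal(nrow(f2), 6)
  # all points off-grid, or one remaining class: untrainable
  all_off <- label_endemicity(survey_tbl(site_id = c("q", "r"), x = c(99, 98),
                                         y = c(99, 98), cases = c(1L, 0L),
                                         country = "C", source = "s"))
  expect_error(suppressMessages(build_model_frame(all_off, NULL, stk)),
               "both classes")
})

test_that("survey rows carry weight 1 and pseudo-absences weight in (0,1]", {
  frame <- small_frame()
  surv <- frame[frame$origin == "survey", ]
  pa <- frame[frame$origin == "pseudo_absence", ]
  expect_true(all(surv$weight == 1))
  expect_true(all(pa$weight > 0 & pa$weight <= 1))
  expect_true(all(pa$label == 0))
  # the published count rule: as many pseudo-absences as survey records
  expect_equal(nrow(pa), nrow(surv))
})
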