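#' Load survey points and collapse spatial duplicates
#'
#' Reads a delimited survey table (columns `site_id`, `x`, `y`, `cases`,
#' `country`, `source`) and collapses records with exactly identical
#' coordinates to one record. On a label conflict at a duplicated site,
#' presence wins: a confirmed case cannot be negated by a second survey.
#' Deduplication is exact-coordinate -- no tolerance merging; upstream
#' rounding is the caller's responsibility.
#'
#' @param path CSV file path, or a data frame already in memory.
#' @return Tibble of unique occurrence records; the number of collapsed
#'   rows is reported with a message and stored in the `n_collapsed`
#'   attribute.
#' @export
load_and_dedupe <- function(path) {
  rec <- if (is.data.frame(path)) tibble::as_tibble(path) else {
    if (!file.exists(path)) stop(sprintf("survey file not found: %s", path), call. = FALSE)
    tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  }
  needed <- c("site_id", "x", "y", "cases", "country", "source")
  missing <- setdiff(needed, names(rec))
  if (length(missing) > 0) {
    stop(sprintf("survey table lacks column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.numeric(rec$x) || !is.numeric(rec$y) || anyNA(rec$x) || anyNA(rec$y)) {
    stop("survey coordinates must be numeric and non-missing", call. = FALSE)
  }
  n_in <- nrow(rec)
  out <- dplyr::ungroup(dplyr::slice_head(
    dplyr::arrange(dplyr::group_by(rec, .data$x, .data$y),
                   dplyr::desc(.data$cases > 0)), n = 1))
  out <- dplyr::arrange(out, match(out$site_id, rec$site_id))
  n_collapsed <- n_in - nrow(out)
  if (n_collapsed > 0) {
    message(sprintf("collapsed %d spatially duplicated record(s)", n_collapsed))
  }
  attr(out, "n_collapsed") <- n_collapsed
  out
}

#' Label endemicity of survey records
#'
#' A site is endemic (label 1) iff it reported confirmed cases
#' (`cases > 0`), else non-endemic (label 0). Surveyed absences are treated
#' as true absences and, like presences, carry weight 1.
#'
#' @param records Tibble from [load_and_dedupe()].
#' @return The records with `label`, `weight` (= 1) and
#'   `origin = "survey"` columns added.
#' @export
label_endemicity <- function(records) {
  dplyr::mutate(tibble::as_tibble(records),
                label = as.integer(.data$cases > 0),
                weight = 1, origin = "survey")
}

#' Rescale country evidence scores to pseudo-absence weights
#'
#' Only countries with an evidence score below 0 (evidence of absence) are
#' eligible to host pseudo-absences. Their weights are a min-max rescaling
#' of the absolute score onto `[floor, 1]`: the most negative score (the
#' strongest evidence of absence) maps to 1, the least negative to the
#' configurable floor, so confident absences count more and no eligible
#' country is weightless. With a single eligible country the weight is 1.
#'
#' @param evidence Tibble with columns `country` and `score`, or a path to
#'   such a CSV.
#' @param floor Weight assigned to the least negative eligible score
#'   (default 0.25).
#' @return Tibble with `country`, `score`, `weight` for eligible countries.
#' @export
rescale_evidence <- function(evidence, floor = 0.25) {
  if (!is.data.frame(evidence)) {
    evidence <- tibble::as_tibble(utils::read.csv(evidence, stringsAsFactors = FALSE))
  }
  stopifnot(all(c("country", "score") %in% names(evidence)),
            floor > 0, floor <= 1)
  elig <- dplyr::filter(tibble::as_tibble(evidence), .data$score < 0)
  if (nrow(elig) == 0) {
    stop("no country has an evidence score below 0; cannot place pseudo-absences",
         call. = FALSE)
  }
  a <- abs(elig$score)
  w <- if (diff(range(a)) == 0) rep(1, length(a)) else {
    floor + (1 - floor) * (a - min(a)) / (max(a) - min(a))
  }
  dplyr::mutate(elig, weight = w)
}

#' Sample weighted pseudo-absence points
#'
#' Draws `n` points uniformly (cells with replacement) over the valid cells
#' of the eligible-zone raster whose country has a rescaled weight, placing
#' each point at its cell centre (covariates are constant within a cell, so
#' sub-cell placement is irrelevant). Each point is labelled 0 with origin
#' `"pseudo_absence"` and carries its country's weight. In the published
#' design `n` equals the number of compiled presence and true-absence
#' records.
#'
#' @param eligible_zone_raster `grid_raster` of country indices, masked
#'   outside the area eligible for pseudo-absences.
#' @param weights_by_country Tibble from [rescale_evidence()] plus a
#'   `country_index` column matching the raster values.
#' @param n Number of points to draw.
#' @param rng_seed Integer seed; the draw is reproducible.
#' @return Tibble of pseudo-absence points (`site_id`, `x`, `y`, `cases`,
#'   `country`, `source`, `label`, `weight`, `origin`).
#' @export
sample_pseudo_absences <- function(eligible_zone_raster, weights_by_country, n,
                                   rng_seed = 1) {
  stopifnot(n >= 1, all(c("country", "country_index", "weight") %in%
                          names(weights_by_country)))
  r <- eligible_zone_raster
  cc <- cell_centres(r$spec)
  vals <- as.vector(t(r$values))
  ok <- !as.vector(t(r$mask)) & vals %in% weights_by_country$country_index
  if (!any(ok)) stop("no eligible cells to sample pseudo-absences from", call. = FALSE)
  cells <- which(ok)
  draw <- withr_seed(rng_seed, sample(cells, n, replace = TRUE))
  ci <- match(vals[draw], weights_by_country$country_index)
  tibble::tibble(
    site_id = sprintf("pa_%05d", seq_len(n)),
    x = cc$x[draw], y = cc$y[draw], cases = 0L,
    country = weights_by_country$country[ci],
    source = "pseudo_absence",
    label = 0L, weight = weights_by_country$weight[ci],
    origin = "pseudo_absence")
}

#' Assemble the weighted training frame
#'
#' Extracts the covariates of every survey and pseudo-absence point from
#' the stack, drops rows falling outside the extent or on nodata cells
#' (count reported), and returns the frame all learners consume. Presences
#' and surveyed absences carry weight 1; pseudo-absences carry their
#' country's rescaled weight in `(0, 1]`.
#'
#' @param labelled Tibble from [label_endemicity()].
#' @param pseudo Tibble from [sample_pseudo_absences()] (or NULL).
#' @param stack A `covariate_stack`.
#' @return A `model_frame` tibble (`label`, `weight`, `x`, `y`, `origin`
#'   plus covariate columns; covariate names kept in the `covariates`
#'   attribute).
#' @export
build_model_frame <- function(labelled, pseudo, stack) {
  pts <- dplyr::bind_rows(tibble::as_tibble(labelled), tibble::as_tibble(pseudo))
  keep <- c("site_id", "label", "weight", "x", "y", "origin")
  pts <- pts[intersect(keep, names(pts))]
  ext <- suppressWarnings(extract_at_points(stack, pts))
  n_drop <- sum(!ext$valid)
  if (n_drop > 0) {
    message(sprintf("dropped %d point(s) with missing covariates", n_drop))
  }
  frame <- dplyr::select(dplyr::filter(ext, .data$valid), -"valid")
  if (nrow(frame) == 0 || length(unique(frame$label)) < 2) {
    stop("model frame does not contain both classes; models untrainable",
         call. = FALSE)
  }
  attr(frame, "covariates") <- stack$names
  class(frame) <- c("model_frame", class(frame))
  frame
}
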