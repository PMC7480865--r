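#' Binarise a suitability surface
#'
#' A valid cell becomes 1 iff its suitability is greater than or equal to
#' the threshold (presence-inclusive at the cut-off); masked cells stay
#' masked.
#'
#' @param suitability A `grid_raster` with values in `[0, 1]`.
#' @param threshold Threshold in `[0, 1]`.
#' @return A `binary_map`: a `grid_raster` of 0/1 with the threshold kept
#'   in the `threshold` attribute.
#' @export
binarize <- function(suitability, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  out <- grid_raster(suitability$spec,
                     ifelse(suitability$mask, NA_real_,
                            as.numeric(suitability$values >= threshold)),
                     suitability$mask)
  attr(out, "threshold") <- threshold
  class(out) <- c("binary_map", class(out))
  out
}

zone_vector <- function(zones) {
  stopifnot(inherits(zones, "grid_raster"))
  z <- as.vector(t(zones$values))
  z[as.vector(t(zones$mask))] <- NA
  z
}

#' Population at risk per zone, with uncertainty
#'
#' The point estimate per zone is the sum of population over that zone's
#' cells classified suitable in the point binary map. The uncertainty
#' interval repeats the same sum for every ensemble-member binary map and
#' takes the 2.5% / 97.5% empirical quantiles -- summarising the replicate
#' predictions rather than the cellwise bound surfaces, so each bound is a
#' realisable map total.
#'
#' @param binary Point-estimate `binary_map`.
#' @param population Aligned `grid_raster` of population counts (>= 0).
#' @param member_binaries List of aligned member `binary_map`s (may be
#'   empty: interval collapses to the point estimate).
#' @param zones Aligned `grid_raster` of zone indices.
#' @param zone_names Optional tibble with `zone_index`, `zone` columns.
#' @return A `risk_summary`: list with `zones` (tibble: `zone`,
#'   `population_at_risk`, `lower`, `upper`) and `overall` (one-row
#'   tibble). Zone sums reconcile exactly with the overall total.
#' @export
population_at_risk <- function(binary, population, member_binaries = list(),
                               zones, zone_names = NULL) {
  stop_if_misaligned(binary, population, "binary", "population")
  stop_if_misaligned(binary, zones, "binary", "zones")
  stopifnot(all(raster_values(population) >= 0))
  z <- zone_vector(zones)
  pop <- as.vector(t(population$values))
  sum_by_zone <- function(bin) {
    b <- as.vector(t(bin$values))
    sel <- !is.na(b) & b == 1 & !is.na(pop) & !is.na(z)
    out <- tapply(pop[sel], z[sel], sum)
    full <- stats::setNames(rep(0, length(unique(stats::na.omit(z)))),
                            sort(unique(stats::na.omit(z))))
    full[names(out)] <- out
    full
  }
  point <- sum_by_zone(binary)
  member_totals <- purrr::map(member_binaries, sum_by_zone)
  zone_bounds <- if (length(member_totals) > 0) {
    m <- do.call(rbind, member_totals)
    list(lower = apply(m, 2, stats::quantile, 0.025, names = FALSE),
         upper = apply(m, 2, stats::quantile, 0.975, names = FALSE))
  } else list(lower = point, upper = point)
  zone_idx <- as.numeric(names(point))
  zone_lab <- if (!is.null(zone_names)) {
    zone_names$zone[match(zone_idx, zone_names$zone_index)]
  } else as.character(zone_idx)
  ztab <- tibble::tibble(zone = zone_lab, zone_index = zone_idx,
                         population_at_risk = as.numeric(point),
                         lower = as.numeric(zone_bounds$lower),
                         upper = as.numeric(zone_bounds$upper))
  overall_members <- purrr::map_dbl(member_totals, sum)
  overall <- tibble::tibble(
    population_at_risk = sum(point),
    lower = if (length(overall_members)) stats::quantile(overall_members, 0.025,
                                                         names = FALSE) else sum(point),
    upper = if (length(overall_members)) stats::quantile(overall_members, 0.975,
                                                         names = FALSE) else sum(point))
  structure(list(zones = ztab, overall = overall), class = "risk_summary")
}

#' @export
print.risk_summary <- function(x, ...) {
  cat(sprintf("<risk_summary> %d zones; total population at risk %.0f (%.0f-%.0f)\n",
              nrow(x$zones), x$overall$population_at_risk,
              x$overall$lower, x$overall$upper))
  invisible(x)
}

#' Tidy per-zone population at risk
#'
#' @param x A `risk_summary`.
#' @param ... Unused.
#' @return The per-zone tibble.
#' @method tidy risk_summary
#' @export
tidy.risk_summary <- function(x, ...) x$zones

#' Overall population-at-risk summary
#'
#' @param x A `risk_summary`.
#' @param ... Unused.
#' @return One-row tibble with the overall total and interval.
#' @method glance risk_summary
#' @export
glance.risk_summary <- function(x, ...) x$overall

#' Overlap two binary risk maps
#'
#' Combines two aligned binary maps (e.g. podoconiosis and lymphatic
#' filariasis suitability) into a four-class map -- neither, first-only,
#' second-only, both -- and sums population per class. Class populations
#' partition the total population of jointly valid cells.
#'
#' @param a,b Aligned `binary_map`s.
#' @param population Aligned population `grid_raster`.
#' @return List with `class_map` (a `grid_raster` coded 0 = neither,
#'   1 = a-only, 2 = b-only, 3 = both) and `table` (tibble `class`,
#'   `population`).
#' @export
overlap_binary <- function(a, b, population) {
  stop_if_misaligned(a, b, "first binary", "second binary")
  stop_if_misaligned(a, population, "binary", "population")
  cls <- a$values + 2 * b$values        # NA propagates through masks
  class_map <- grid_raster(a$spec, cls, a$mask | b$mask)
  labels <- c(`0` = "neither", `1` = "a_only", `2` = "b_only", `3` = "both")
  cv <- as.vector(t(class_map$values)); pv <- as.vector(t(population$values))
  ok <- !is.na(cv) & !is.na(pv)
  sums <- tapply(pv[ok], cv[ok], sum)
  tab <- tibble::tibble(class = unname(labels),
                        population = as.numeric(sums[names(labels)]))
  tab$population[is.na(tab$population)] <- 0
  list(class_map = class_map, table = tab)
}

#' Classify implementation units by environmental suitability
#'
#' An implementation unit (IU) is suitable iff the fraction of its valid
#' cells classified suitable exceeds `min_fraction`; the default 0 makes
#' any suitable cell sufficient -- the permissive rule, which favours not
#' missing potentially endemic districts. Suitable IUs that are not yet
#' mapped need community-level mapping. IUs with no valid cells are
#' flagged indeterminate and excluded from the shares' denominators.
#'
#' @param binary A `binary_map`.
#' @param iu_zones Aligned `grid_raster` of IU indices.
#' @param mapped_flags Tibble with `iu_index` and logical `mapped`.
#' @param min_fraction Suitable-cell fraction an IU must exceed (default 0).
#' @return Tibble: `iu_index`, `n_cells`, `n_suitable`,
#'   `suitable_cell_fraction`, `suitable`, `mapped`, `needs_mapping`,
#'   `indeterminate`.
#' @export
classify_ius <- function(binary, iu_zones, mapped_flags, min_fraction = 0) {
  stop_if_misaligned(binary, iu_zones, "binary", "IU zones")
  stopifnot(min_fraction >= 0, min_fraction < 1)
  z <- zone_vector(iu_zones)
  b <- as.vector(t(binary$values))
  all_ius <- sort(unique(stats::na.omit(z)))
  tab <- purrr::map_dfr(all_ius, function(iu) {
    in_iu <- !is.na(z) & z == iu
    valid <- in_iu & !is.na(b)
    n <- sum(valid); ns <- sum(b[valid] == 1)
    tibble::tibble(iu_index = iu, n_cells = n, n_suitable = ns,
                   suitable_cell_fraction = if (n > 0) ns / n else NA_real_,
                   indeterminate = n == 0)
  })
  if (any(tab$indeterminate)) {
    message(sprintf("%d IU(s) with no valid cells flagged indeterminate",
                    sum(tab$indeterminate)))
  }
  tab$suitable <- !tab$indeterminate & tab$suitable_cell_fraction > min_fraction
  tab$mapped <- mapped_flags$mapped[match(tab$iu_index, mapped_flags$iu_index)]
  tab$mapped[is.na(tab$mapped)] <- FALSE
  tab$needs_mapping <- tab$suitable & !tab$mapped
  tab
}

#' Reported share percentages
#'
#' `100 * numerator / denominator`, rounded half-up to one decimal -- the
#' convention of the reporting layer (e.g. "1,655 (29.0%) IUs"). Rounding
#' is applied only here, never inside computations.
#'
#' @param numerators Numeric vector (may be named).
#' @param denominator Positive scalar.
#' @return Percentages at one decimal, same names as `numerators`.
#' @export
share_percentages <- function(numerators, denominator) {
  if (length(denominator) != 1 || denominator <= 0) {
    stop("denominator must be a single positive number", call. = FALSE)
  }
  pct <- 100 * numerators / denominator
  floor(pct * 10 + 0.5) / 10
}
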