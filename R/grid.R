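#' Define a raster grid
#'
#' A `grid_spec` fixes the geometry every raster in a pipeline shares: the
#' number of rows and columns, the coordinates of the lower-left corner of
#' the extent, the (square) cell size and a free-form CRS label. Coordinates
#' are planar throughout the package -- for real data this means a projected
#' CRS in kilometres; the synthetic scenarios use a plain planar
#' kilometre grid so Euclidean distances are exact.
#'
#' Conventions, applied consistently everywhere:
#' * row 1 is the northernmost row (raster convention);
#' * a cell owns the half-open square `[x0, x0 + cell) x [y0, y0 + cell)`
#'   horizontally and, reading top-down, a point on a shared edge belongs to
#'   the cell on its right (in x) and on its top (in y);
#' * all statistics ignore cells flagged as nodata.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param x_min,y_min Coordinates of the lower-left corner of the extent.
#' @param cell_size Side length of a (square) cell, in the same units as the
#'   coordinates (kilometres for the synthetic scenarios).
#' @param crs_label Opaque string naming the coordinate reference system.
#' @return An object of class `grid_spec`.
#' @export
#' @examples
#' grid_spec(120, 120, cell_size = 5)
grid_spec <- function(n_rows, n_cols, x_min = 0, y_min = 0, cell_size = 5,
                      crs_label = "planar-km") {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0,
            is.finite(x_min), is.finite(y_min))
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         x_min = as.numeric(x_min), y_min = as.numeric(y_min),
         cell_size = as.numeric(cell_size), crs_label = as.character(crs_label)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, cell %g, origin (%g, %g), crs '%s'\n",
              x$n_rows, x$n_cols, x$cell_size, x$x_min, x$y_min, x$crs_label))
  invisible(x)
}

spec_y_max <- function(spec) spec$y_min + spec$n_rows * spec$cell_size
spec_x_max <- function(spec) spec$x_min + spec$n_cols * spec$cell_size

#' Test whether two grid specs are aligned
#'
#' Two specs are aligned iff every field is equal; all multi-raster
#' operations require alignment.
#'
#' @param a,b `grid_spec` objects.
#' @return Logical scalar.
#' @export
specs_aligned <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$x_min, b$x_min)) && isTRUE(all.equal(a$y_min, b$y_min)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) && a$crs_label == b$crs_label
}

#' Cell-centre coordinates of a grid
#'
#' @param spec A `grid_spec`.
#' @return A tibble with columns `row`, `col`, `x`, `y`, one row per cell in
#'   row-major order (row 1 = northernmost first).
#' @export
cell_centres <- function(spec) {
  y_max <- spec_y_max(spec)
  grid <- tidyr::expand_grid(row = seq_len(spec$n_rows), col = seq_len(spec$n_cols))
  dplyr::mutate(grid,
                x = spec$x_min + (.data$col - 0.5) * spec$cell_size,
                y = y_max - (.data$row - 0.5) * spec$cell_size)
}

# Map point coordinates to (row, col); points outside the half-open extent
# get NA. Edge ownership: right cell in x, top cell in y.
point_to_cell <- function(spec, x, y) {
  cs <- spec$cell_size
  y_max <- spec_y_max(spec)
  col <- floor((x - spec$x_min) / cs) + 1
  d <- (y_max - y) / cs
  row <- floor(d) + 1
  on_edge <- d == floor(d) & d >= 1          # shared horizontal edge -> upper cell
  row[on_edge] <- d[on_edge]
  bad <- !is.finite(x) | !is.finite(y) | d <= 0 |
    col < 1 | col > spec$n_cols | row < 1 | row > spec$n_rows
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Construct a raster on a grid
#'
#' A `grid_raster` couples a `grid_spec` with a numeric value matrix and a
#' logical nodata mask of the same shape. Masked cells are excluded from
#' every downstream statistic; any operation that touches a masked cell
#' yields a masked cell.
#'
#' @param spec A `grid_spec`.
#' @param values Numeric matrix of dim `(n_rows, n_cols)`; row 1 is the
#'   northernmost row. Non-finite entries are masked automatically.
#' @param mask Optional logical matrix, `TRUE` where the cell is nodata.
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(spec, values, mask = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  values <- matrix(as.numeric(values), spec$n_rows, spec$n_cols)
  if (is.null(mask)) mask <- matrix(FALSE, spec$n_rows, spec$n_cols)
  stopifnot(identical(dim(values), dim(mask)))
  mask <- mask | !is.finite(values)
  values[mask] <- NA_real_
  structure(list(spec = spec, values = values, mask = mask),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- raster_values(x)
  cat(sprintf("<grid_raster> %d x %d, %d valid cells, range [%g, %g]\n",
              x$spec$n_rows, x$spec$n_cols, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Valid (unmasked) values of a raster
#'
#' @param r A `grid_raster`.
#' @return Numeric vector of the values at valid cells.
#' @export
raster_values <- function(r) r$values[!r$mask]

#' Tidy a raster into a cell table
#'
#' @param x A `grid_raster`.
#' @param ... Unused.
#' @return A tibble with `row`, `col`, `x`, `y`, `value` (NA where masked).
#' @method tidy grid_raster
#' @export
tidy.grid_raster <- function(x, ...) {
  out <- cell_centres(x$spec)
  out$value <- as.vector(t(x$values))
  out
}

stop_if_misaligned <- function(a, b, what_a = "first", what_b = "second") {
  if (!specs_aligned(a$spec, b$spec)) {
    stop(sprintf("rasters are not aligned: %s vs %s layer", what_a, what_b),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Resample a raster onto a target grid
#'
#' Bilinear resampling evaluates, at each target cell centre, the bilinear
#' interpolation of the four surrounding source cell centres; any target
#' cell whose (positively weighted) source neighbours include a masked or
#' out-of-extent cell is masked -- the conservative choice at coastlines.
#' Nearest-neighbour assigns the value of the closest source cell centre.
#' Resampling to a grid identical to the source is the identity.
#'
#' @param src A `grid_raster`.
#' @param target A `grid_spec` to resample onto.
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return A `grid_raster` aligned to `target`.
#' @export
resample_to_grid <- function(src, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  sspec <- src$spec
  if (spec_x_max(sspec) <= target$x_min || sspec$x_min >= spec_x_max(target) ||
      spec_y_max(sspec) <= target$y_min || sspec$y_min >= spec_y_max(target)) {
    stop("source and target extents do not overlap", call. = FALSE)
  }
  cc <- cell_centres(target)
  # fractional source indices: source col j has centre at u = j, row i at v = i
  u <- (cc$x - sspec$x_min) / sspec$cell_size + 0.5
  v <- (spec_y_max(sspec) - cc$y) / sspec$cell_size + 0.5
  nr <- sspec$n_rows; nc <- sspec$n_cols
  val_at <- function(i, j) {
    ok <- i >= 1 & i <= nr & j >= 1 & j <= nc & !is.na(i) & !is.na(j)
    out <- rep(NA_real_, length(i))
    idx <- cbind(i[ok], j[ok])
    out[ok] <- ifelse(src$mask[idx], NA_real_, src$values[idx])
    out
  }
  if (method == "nearest") {
    i <- pmin(pmax(round(v), 1), nr); j <- pmin(pmax(round(u), 1), nc)
    outside <- u < 0.5 | u > nc + 0.5 | v < 0.5 | v > nr + 0.5
    vals <- val_at(i, j)
    vals[outside] <- NA_real_
  } else {
    j0 <- floor(u); i0 <- floor(v)
    tx <- u - j0; ty <- v - i0
    # neighbours with zero weight are not required to exist or be valid,
    # which makes identity resampling exact on the grid edges
    w00 <- (1 - tx) * (1 - ty); w01 <- tx * (1 - ty)
    w10 <- (1 - tx) * ty;       w11 <- tx * ty
    acc <- rep(0, nrow(cc)); bad <- rep(FALSE, nrow(cc))
    take <- function(i, j, w) {
      use <- w > 0
      vv <- val_at(i, j)
      bad <<- bad | (use & is.na(vv))
      acc <<- acc + ifelse(use & !is.na(vv), w * vv, 0)
    }
    take(i0,     j0,     w00)
    take(i0,     j0 + 1, w01)
    take(i0 + 1, j0,     w10)
    take(i0 + 1, j0 + 1, w11)
    vals <- acc
    vals[bad] <- NA_real_
  }
  grid_raster(target, matrix(vals, target$n_rows, target$n_cols, byrow = TRUE))
}

#' Euclidean distance to the nearest feature cell
#'
#' Given a raster whose valid cells are 0/1 feature indicators, returns a
#' raster whose every valid cell holds the straight-line (Euclidean)
#' distance, in coordinate units (km), from its centre to the centre of the
#' nearest feature cell. Feature cells hold 0. Distances are centre to
#' centre; sub-cell geometry is not modelled. Typical use: the
#' distance-to-water covariate from a river/water-body mask.
#'
#' @param feature_mask A `grid_raster` with values in `{0, 1}`.
#' @return A `grid_raster` of distances; masked where the input is masked.
#' @export
distance_to_features <- function(feature_mask) {
  spec <- feature_mask$spec
  feat <- !feature_mask$mask & feature_mask$values == 1
  if (!any(feat)) stop("feature mask has no feature (value 1) cells", call. = FALSE)
  cc <- cell_centres(spec)
  fidx <- which(t(feat))               # row-major order matches cell_centres
  fx <- cc$x[fidx]; fy <- cc$y[fidx]
  n <- nrow(cc)
  d2 <- rep(Inf, n)
  # accumulate min over features in chunks; desk-scale grids keep this cheap
  chunk <- max(1L, floor(4e6 / n))
  for (s in seq(1, length(fx), by = chunk)) {
    e <- min(s + chunk - 1, length(fx))
    block <- outer(cc$x, fx[s:e], "-")^2 + outer(cc$y, fy[s:e], "-")^2
    d2 <- pmin(d2, apply(block, 1, min))
  }
  out <- grid_raster(spec, matrix(sqrt(d2), spec$n_rows, spec$n_cols, byrow = TRUE))
  out$mask <- out$mask | feature_mask$mask
  out$values[out$mask] <- NA_real_
  out
}

#' Bundle aligned rasters into a covariate stack
#'
#' @param layers Named list of `grid_raster` objects, all on one grid.
#' @return An object of class `covariate_stack`.
#' @export
covariate_stack <- function(layers) {
  stopifnot(length(layers) >= 1, !is.null(names(layers)),
            !anyDuplicated(names(layers)))
  purrr::walk(layers, function(l) stopifnot(inherits(l, "grid_raster")))
  spec <- layers[[1]]$spec
  purrr::iwalk(layers, function(l, nm) {
    if (!specs_aligned(l$spec, spec)) {
      stop(sprintf("layer '%s' is not aligned to the stack grid", nm), call. = FALSE)
    }
  })
  structure(list(names = names(layers), layers = layers, spec = spec),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("<covariate_stack> %d layers on %d x %d grid: %s\n",
              length(x$layers), x$spec$n_rows, x$spec$n_cols,
              paste(x$names, collapse = ", ")))
  invisible(x)
}

#' Cells valid in every layer of a stack
#'
#' @param stack A `covariate_stack`.
#' @return Logical matrix, `TRUE` where the cell is valid in all layers.
#' @export
stack_valid_mask <- function(stack) {
  Reduce(`&`, purrr::map(stack$layers, function(l) !l$mask))
}

#' Covariate table of all stack-valid cells
#'
#' @param stack A `covariate_stack`.
#' @return Tibble with `row`, `col`, `x`, `y` and one column per covariate,
#'   one row per stack-valid cell.
#' @export
stack_cell_table <- function(stack) {
  cc <- cell_centres(stack$spec)
  for (nm in stack$names) {
    cc[[nm]] <- as.vector(t(stack$layers[[nm]]$values))
  }
  valid <- as.vector(t(stack_valid_mask(stack)))
  cc[valid, , drop = FALSE]
}

#' Extract covariate values at points
#'
#' Each point is assigned to the cell containing it under the half-open
#' ownership convention; points outside the extent or in cells invalid in
#' any layer are flagged `valid = FALSE` (their covariates are NA) and a
#' warning summarises the count.
#'
#' @param stack A `covariate_stack`.
#' @param points Data frame with columns `x` and `y` (extra columns pass
#'   through).
#' @return The input tibble plus one column per covariate and a `valid`
#'   flag.
#' @export
extract_at_points <- function(stack, points) {
  points <- tibble::as_tibble(points)
  if (nrow(points) == 0) stop("no points supplied", call. = FALSE)
  stopifnot(all(c("x", "y") %in% names(points)))
  rc <- point_to_cell(stack$spec, points$x, points$y)
  inside <- !is.na(rc$row)
  for (nm in stack$names) {
    lay <- stack$layers[[nm]]
    v <- rep(NA_real_, nrow(points))
    idx <- cbind(rc$row[inside], rc$col[inside])
    v[inside] <- ifelse(lay$mask[idx], NA_real_, lay$values[idx])
    points[[nm]] <- v
  }
  points$valid <- inside &
    !Reduce(`|`, purrr::map(stack$names, function(nm) is.na(points[[nm]])))
  if (any(!points$valid)) {
    warning(sprintf("%d of %d points fall outside the extent or on nodata cells",
                    sum(!points$valid), nrow(points)), call. = FALSE)
  }
  points
}
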