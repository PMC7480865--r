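# Minimal single-band float32 GeoTIFF codec.
#
# The pipeline only ever needs one raster format: single-band, float32,
# uncompressed, little-endian, with ModelPixelScale / ModelTiepoint
# georeferencing, a GDAL-style ASCII nodata tag and the CRS label carried in
# the GeoTIFF citation key. Values are stored top row first, matching the
# grid_raster convention. Classic TIFF only (no BigTIFF, no compression,
# no tiles); anything else is rejected with an explicit error naming the
# file rather than silently misread.

TIFF_TAGS <- c(
  image_width = 256L, image_length = 257L, bits_per_sample = 258L,
  compression = 259L, photometric = 262L, strip_offsets = 273L,
  samples_per_pixel = 277L, rows_per_strip = 278L, strip_byte_counts = 279L,
  planar_config = 284L, sample_format = 339L,
  model_pixel_scale = 33550L, model_tiepoint = 33922L,
  geo_key_directory = 34735L, geo_ascii_params = 34737L, gdal_nodata = 42113L
)

#' Write a raster as a single-band float32 GeoTIFF
#'
#' Masked cells are stored as the `nodata` sentinel (and re-masked on read).
#' Values are stored as IEEE float32, so a write/read round trip is exact
#' for values representable in 32-bit floats.
#'
#' @param r A `grid_raster`.
#' @param path Output file path.
#' @param nodata Sentinel value written in masked cells and recorded in the
#'   nodata tag; must be exactly representable in float32 (the default
#'   -9999 is).
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path, nodata = -9999) {
  stopifnot(inherits(r, "grid_raster"))
  spec <- r$spec
  vals <- r$values
  vals[r$mask] <- nodata
  pix <- as.vector(t(vals))                      # row-major, top row first
  n_pix_bytes <- length(pix) * 4L

  nodata_str <- c(charToRaw(format(nodata, scientific = FALSE)), as.raw(0))
  crs_str <- c(charToRaw(spec$crs_label), as.raw(0))
  # GeoKeyDirectory: version 1.1.0, one key: GTCitationGeoKey in GeoAsciiParams
  geokeys <- as.integer(c(1, 1, 0, 1, 1026, 34737, length(crs_str), 0))

  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con); u16(42L)
  data_off <- 8L
  ifd_off <- data_off + n_pix_bytes
  u32(ifd_off)
  writeBin(pix, con, size = 4, endian = "little")

  entries <- list(
    list(TIFF_TAGS[["image_width"]],      3L, 1L, spec$n_cols),
    list(TIFF_TAGS[["image_length"]],     3L, 1L, spec$n_rows),
    list(TIFF_TAGS[["bits_per_sample"]],  3L, 1L, 32L),
    list(TIFF_TAGS[["compression"]],      3L, 1L, 1L),
    list(TIFF_TAGS[["photometric"]],      3L, 1L, 1L),
    list(TIFF_TAGS[["strip_offsets"]],    4L, 1L, data_off),
    list(TIFF_TAGS[["samples_per_pixel"]],3L, 1L, 1L),
    list(TIFF_TAGS[["rows_per_strip"]],   4L, 1L, spec$n_rows),
    list(TIFF_TAGS[["strip_byte_counts"]],4L, 1L, n_pix_bytes),
    list(TIFF_TAGS[["planar_config"]],    3L, 1L, 1L),
    list(TIFF_TAGS[["sample_format"]],    3L, 1L, 3L),
    list(TIFF_TAGS[["model_pixel_scale"]],12L, 3L,
         c(spec$cell_size, spec$cell_size, 0)),
    list(TIFF_TAGS[["model_tiepoint"]],  12L, 6L,
         c(0, 0, 0, spec$x_min, spec_y_max(spec), 0)),
    list(TIFF_TAGS[["geo_key_directory"]],3L, length(geokeys), geokeys),
    list(TIFF_TAGS[["geo_ascii_params"]], 2L, length(crs_str), crs_str),
    list(TIFF_TAGS[["gdal_nodata"]],      2L, length(nodata_str), nodata_str)
  )

  type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `12` = 8L)
  payload_size <- function(e) type_size[[as.character(e[[2]])]] * e[[3]]
  # out-of-line payloads follow the IFD
  out_off <- ifd_off + 2L + 12L * length(entries) + 4L
  u16(length(entries))
  offsets <- integer(0)
  for (e in entries) {
    u16(e[[1]]); u16(e[[2]]); u32(e[[3]])
    if (payload_size(e) <= 4) {
      if (e[[2]] == 3L) { u16(e[[4]]); if (e[[3]] == 1L) u16(0L) } else u32(e[[4]])
    } else {
      u32(out_off)
      offsets <- c(offsets, out_off)
      out_off <- out_off + payload_size(e)
      if (out_off %% 2 == 1) out_off <- out_off + 1L   # word alignment
    }
  }
  u32(0L)                                              # no next IFD
  pos <- ifd_off + 2L + 12L * length(entries) + 4L
  for (e in entries) {
    if (payload_size(e) <= 4) next
    if (e[[2]] == 12L) writeBin(as.numeric(e[[4]]), con, size = 8, endian = "little")
    else if (e[[2]] == 2L) writeBin(as.raw(e[[4]]), con)
    else u16(e[[4]])
    pos <- pos + payload_size(e)
    if (pos %% 2 == 1) { writeBin(as.raw(0), con); pos <- pos + 1L }
  }
  invisible(path)
}

read_u <- function(raw, off, size) {
  # little-endian unsigned integer at 0-based offset
  sum(as.integer(raw[off + seq_len(size)]) * 256^(seq_len(size) - 1))
}

#' Read a single-band float32 GeoTIFF
#'
#' Reads rasters written by [write_raster()] (and any uncompressed,
#' stripped, single-band float32 classic GeoTIFF). Cells equal to the
#' file's nodata sentinel, and non-finite cells, are masked. Multi-band or
#' multi-image files, compressed data and missing georeferencing are
#' explicit errors naming the file.
#'
#' @param path Path to the GeoTIFF.
#' @return A `grid_raster`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop(sprintf("raster file not found: %s", path), call. = FALSE)
  raw <- readBin(path, "raw", file.size(path))
  fail <- function(msg) stop(sprintf("%s: %s", msg, path), call. = FALSE)
  if (length(raw) < 8 || rawToChar(raw[1:2]) != "II" || read_u(raw, 2, 2) != 42)
    fail("not a little-endian classic TIFF")
  ifd_off <- read_u(raw, 4, 4)
  n_entries <- read_u(raw, ifd_off, 2)
  type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `12` = 8L)
  tags <- list()
  for (k in seq_len(n_entries)) {
    e_off <- ifd_off + 2 + 12 * (k - 1)
    tag <- read_u(raw, e_off, 2); type <- read_u(raw, e_off + 2, 2)
    count <- read_u(raw, e_off + 4, 4)
    ts <- type_size[as.character(type)]
    if (is.na(ts)) next                       # unsupported type: ignore tag
    nbytes <- ts * count
    voff <- if (nbytes <= 4) e_off + 8 else read_u(raw, e_off + 8, 4)
    vals <- switch(as.character(type),
      `1` = , `2` = as.integer(raw[voff + seq_len(count)]),
      `3` = vapply(seq_len(count) - 1, function(i) read_u(raw, voff + 2 * i, 2), 0),
      `4` = vapply(seq_len(count) - 1, function(i) read_u(raw, voff + 4 * i, 4), 0),
      `12` = readBin(raw[voff + seq_len(nbytes)], "double", count, size = 8,
                     endian = "little"))
    tags[[as.character(tag)]] <- vals
  }
  if (read_u(raw, ifd_off + 2 + 12 * n_entries, 4) != 0)
    fail("multi-image TIFF not supported")
  g <- function(tag, default = NULL) {
    v <- tags[[as.character(TIFF_TAGS[[tag]])]]
    if (is.null(v)) default else v
  }
  n_cols <- g("image_width"); n_rows <- g("image_length")
  if (is.null(n_cols) || is.null(n_rows)) fail("missing image dimensions")
  if (!identical(g("samples_per_pixel", 1), 1)) fail("multi-band TIFF not supported")
  if (!identical(g("compression", 1), 1)) fail("compressed TIFF not supported")
  if (!identical(g("sample_format", 1), 3) || !identical(g("bits_per_sample", 1), 32))
    fail("only float32 sample data supported")
  scale <- g("model_pixel_scale"); tie <- g("model_tiepoint")
  if (is.null(scale) || is.null(tie)) fail("unreadable georeferencing")
  if (abs(scale[1] - scale[2]) > 1e-9 * scale[1]) fail("non-square cells not supported")
  offs <- g("strip_offsets"); counts <- g("strip_byte_counts")
  if (is.null(offs) || is.null(counts)) fail("missing strip layout")
  pix_raw <- do.call(c, purrr::map2(offs, counts, function(o, n) raw[o + seq_len(n)]))
  pix <- readBin(pix_raw, "double", n_rows * n_cols, size = 4, endian = "little")
  crs_raw <- g("geo_ascii_params")
  crs_label <- if (is.null(crs_raw)) "unknown" else {
    s <- rawToChar(as.raw(crs_raw[crs_raw != 0]))
    if (nzchar(s)) s else "unknown"
  }
  nodata <- g("gdal_nodata")
  nodata <- if (is.null(nodata)) NA_real_ else
    as.numeric(rawToChar(as.raw(nodata[nodata != 0])))
  # tiepoint maps raster (0,0) corner to (x, y_max)
  y_max <- tie[5] - tie[2] * scale[2]
  x_min <- tie[4] - tie[1] * scale[1]
  spec <- grid_spec(n_rows, n_cols, x_min = x_min,
                    y_min = y_max - n_rows * scale[2],
                    cell_size = scale[1], crs_label = crs_label)
  vals <- matrix(pix, n_rows, n_cols, byrow = TRUE)
  mask <- !is.finite(vals)
  if (is.finite(nodata)) mask <- mask | (vals == nodata)
  grid_raster(spec, vals, mask)
}
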