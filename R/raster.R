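#' The twelve climate variable codes
#'
#' The fixed set of bioclimatic layers used throughout: annual mean
#' temperature (BIO1), maximum temperature of the warmest month (BIO5),
#' minimum temperature of the coldest month (BIO6), annual precipitation
#' (BIO12), precipitation of the wettest (BIO16) and driest (BIO17)
#' quarters, potential evapotranspiration annual/wettest/driest
#' (PET.A, PET.W, PET.D), elevation (Elev), climatic moisture (CM) and
#' cloud cover (CC).
#'
#' @return Character vector of the twelve layer codes, in canonical order.
#' @export
climate_codes <- function() {
  c("BIO1", "BIO5", "BIO6", "BIO12", "BIO16", "BIO17",
    "PET.A", "PET.W", "PET.D", "Elev", "CM", "CC")
}

#' Construct a multi-layer climate raster
#'
#' A `climate_raster` is a stack of twelve aligned grids sharing one
#' geographic frame. Grids are row-major from the north-west corner:
#' row 1 is the northernmost row, so latitude decreases with row index.
#' `lon_origin`/`lat_origin` locate the *corner* of the north-west pixel,
#' and `pixel_size` is the pixel edge in arc-minutes.
#'
#' @param values named list of twelve numeric matrices (one per code in
#'   [climate_codes()]), all with identical dimensions.
#' @param lon_origin,lat_origin decimal degrees of the NW pixel corner.
#' @param pixel_size pixel edge length in arc-minutes (> 0).
#' @param mask optional logical matrix of valid pixels; defaults to all
#'   `TRUE`.
#' @return An object of class `climate_raster`.
#' @export
climate_raster <- function(values, lon_origin, lat_origin, pixel_size,
                           mask = NULL) {
  codes <- climate_codes()
  if (!is.list(values) || is.null(names(values)))
    stop("'values' must be a named list of matrices")
  if (!setequal(names(values), codes))
    stop("'values' must contain exactly the twelve layers: ",
         paste(codes, collapse = ", "))
  values <- values[codes]
  dims <- dim(values[[1L]])
  for (code in codes) {
    if (!is.matrix(values[[code]]) || !identical(dim(values[[code]]), dims))
      stop("all layers must be matrices of identical dimensions")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number (arc-minutes)")
  if (is.null(mask)) mask <- matrix(TRUE, dims[1L], dims[2L])
  if (!identical(dim(mask), dims)) stop("'mask' dimensions must match layers")
  elev <- values[["Elev"]][mask]
  if (any(elev < 0, na.rm = TRUE))
    stop("elevation layer must be nonnegative on valid pixels")
  structure(
    list(values = values, lon_origin = lon_origin, lat_origin = lat_origin,
         pixel_size = pixel_size, mask = mask,
         n_rows = dims[1L], n_cols = dims[2L]),
    class = "climate_raster")
}

#' @export
print.climate_raster <- function(x, ...) {
  cat(sprintf("climate_raster: %d x %d pixels, %d layers, %.4g arc-min\n",
              x$n_rows, x$n_cols, length(x$values), x$pixel_size))
  cat(sprintf("  NW corner: (%.4f, %.4f); valid pixels: %d/%d\n",
              x$lon_origin, x$lat_origin, sum(x$mask), length(x$mask)))
  invisible(x)
}

# pixel edge in decimal degrees
pixel_deg <- function(raster) raster$pixel_size / 60

#' Map coordinates to pixel indices
#'
#' Pixel membership uses half-open intervals, `[west, east)` in longitude
#' and `(south, north]` in latitude, so every interior point maps to
#' exactly one pixel.
#'
#' @param raster a [climate_raster()].
#' @param longitude,latitude numeric vectors of decimal degrees.
#' @return Data frame with columns `row`, `col` and logical `inside`
#'   (inside the extent *and* on an unmasked pixel).
#' @export
pixel_index <- function(raster, longitude, latitude) {
  ps <- pixel_deg(raster)
  x <- (longitude - raster$lon_origin) / ps
  y <- (raster$lat_origin - latitude) / ps
  col <- floor(x) + 1L
  # row r covers y in [r-1, r), i.e. latitude in (south, north]
  row <- floor(y) + 1L
  inside <- col >= 1L & col <= raster$n_cols & row >= 1L & row <= raster$n_rows
  valid <- inside
  valid[inside] <- raster$mask[cbind(row[inside], col[inside])]
  data.frame(row = ifelse(inside, row, NA_integer_),
             col = ifelse(inside, col, NA_integer_),
             inside = valid)
}

#' Pixel center coordinates
#'
#' @param raster a [climate_raster()].
#' @param row,col integer pixel indices.
#' @return Data frame with `longitude` and `latitude` of pixel centers.
#' @export
pixel_center <- function(raster, row, col) {
  ps <- pixel_deg(raster)
  data.frame(longitude = raster$lon_origin + (col - 0.5) * ps,
             latitude = raster$lat_origin - (row - 0.5) * ps)
}

#' Climate values of all valid pixels
#'
#' @param raster a [climate_raster()].
#' @return Numeric matrix, one row per valid pixel and one column per
#'   layer; attributes `row` and `col` give the pixel indices.
#' @export
raster_values <- function(raster) {
  idx <- which(raster$mask, arr.ind = TRUE)
  out <- vapply(raster$values, function(m) m[idx], numeric(nrow(idx)))
  out <- matrix(out, nrow = nrow(idx),
                dimnames = list(NULL, names(raster$values)))
  attr(out, "row") <- idx[, 1L]
  attr(out, "col") <- idx[, 2L]
  out
}

#' Latitude of each raster row center
#' @param raster a [climate_raster()].
#' @return Numeric vector, one latitude per row (north to south).
#' @export
row_latitudes <- function(raster) {
  ps <- pixel_deg(raster)
  raster$lat_origin - (seq_len(raster$n_rows) - 0.5) * ps
}

fmt_full <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)

#' Write / read a climate raster as a plain-text grid bundle
#'
#' The bundle is a directory holding `meta.txt` (codes, origin, pixel
#' size, dimensions), one whitespace-delimited grid file per layer, and
#' `mask.txt`. Values are written with 17 significant digits so the
#' round trip is bit-exact.
#'
#' @param raster a [climate_raster()].
#' @param path directory to create/populate.
#' @return `write_climate_raster` returns `path` invisibly;
#'   `read_climate_raster` returns the reconstructed [climate_raster()].
#' @export
write_climate_raster <- function(raster, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- c(
    paste0("codes: ", paste(names(raster$values), collapse = ",")),
    paste0("lon_origin: ", fmt_full(raster$lon_origin)),
    paste0("lat_origin: ", fmt_full(raster$lat_origin)),
    paste0("pixel_size: ", fmt_full(raster$pixel_size)),
    paste0("n_rows: ", raster$n_rows),
    paste0("n_cols: ", raster$n_cols))
  writeLines(meta, file.path(path, "meta.txt"))
  for (code in names(raster$values)) {
    m <- raster$values[[code]]
    lines <- apply(m, 1L, function(r) paste(fmt_full(r), collapse = " "))
    writeLines(lines, file.path(path, paste0(gsub("\\.", "_", code), ".txt")))
  }
  writeLines(apply(raster$mask, 1L, function(r)
    paste(as.integer(r), collapse = " ")), file.path(path, "mask.txt"))
  invisible(path)
}

#' @rdname write_climate_raster
#' @export
read_climate_raster <- function(path) {
  meta <- readLines(file.path(path, "meta.txt"))
  get <- function(key) sub(paste0("^", key, ": "), "",
                           grep(paste0("^", key, ": "), meta, value = TRUE))
  codes <- strsplit(get("codes"), ",")[[1L]]
  n_rows <- as.integer(get("n_rows"))
  n_cols <- as.integer(get("n_cols"))
  read_grid <- function(file, what = numeric()) {
    matrix(scan(file, what = what, quiet = TRUE), n_rows, n_cols, byrow = TRUE)
  }
  values <- lapply(codes, function(code)
    read_grid(file.path(path, paste0(gsub("\\.", "_", code), ".txt"))))
  names(values) <- codes
  mask <- read_grid(file.path(path, "mask.txt")) > 0
  climate_raster(values,
                 lon_origin = as.numeric(get("lon_origin")),
                 lat_origin = as.numeric(get("lat_origin")),
                 pixel_size = as.numeric(get("pixel_size")),
                 mask = mask)
}
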