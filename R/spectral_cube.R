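#' Spectral cube container
#'
#' A `spectral_cube` is a 3-D raster `values[row, col, band]` together with
#' its [wavelength_grid()] and a kind flag: `"raw"` for uncalibrated sensor
#' counts (DN, constrained to the 12-bit range 0-4095) or `"reflectance"`
#' for calibrated, non-negative reflectance fractions.
#'
#' @param values 3-D numeric array indexed `[row, col, band]`.
#' @param grid A [wavelength_grid()] whose `count` equals `dim(values)[3]`.
#' @param kind `"raw"` or `"reflectance"`.
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(values, grid, kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("values must be a 3-D array [row, col, band]")
  }
  if (!inherits(grid, "wavelength_grid")) stop("grid must be a wavelength_grid")
  if (dim(values)[3] != grid$count) {
    stop(sprintf("cube has %d band planes but grid declares %d",
                 dim(values)[3], grid$count))
  }
  if (!all(is.finite(values))) stop("cube values must all be finite")
  if (kind == "raw") {
    if (min(values) < 0 || max(values) > 4095) {
      stop("raw DN values must lie in the 12-bit range [0, 4095]")
    }
  } else {
    if (min(values) < 0) stop("reflectance values must be non-negative")
  }
  structure(list(values = values, grid = grid, kind = kind),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<spectral_cube:%s> %d x %d pixels, %d bands (%.4g-%.4g nm)\n",
              x$kind, d[1], d[2], d[3],
              x$grid$band_centers[1], x$grid$band_centers[d[3]]))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$values)

#' Rectangular region helper
#'
#' Builds a logical pixel mask for a rectangular region given as 1-based
#' inclusive row and column ranges (the convention used throughout this
#' package).
#'
#' @param shape Integer vector `c(rows, cols)`.
#' @param rows,cols Length-2 integer vectors `c(first, last)`, inclusive.
#' @return Logical matrix of dimension `shape`.
#' @export
rect_mask <- function(shape, rows, cols) {
  if (rows[1] < 1L || rows[2] > shape[1] || cols[1] < 1L || cols[2] > shape[2] ||
      rows[1] > rows[2] || cols[1] > cols[2]) {
    stop("rectangle out of bounds or empty")
  }
  m <- matrix(FALSE, shape[1], shape[2])
  m[rows[1]:rows[2], cols[1]:cols[2]] <- TRUE
  m
}

#' Load a region-of-interest mask from a PNG file
#'
#' Nonzero pixels are in-region. Color masks are collapsed with "any channel
#' nonzero". The mask must match the spatial shape of the raster it will be
#' applied to, and must select at least one pixel.
#'
#' @param path PNG file path.
#' @param shape Expected `c(rows, cols)` of the target raster.
#' @return Logical matrix; `attr(, "n_pixels")` gives the in-region count.
#' @export
load_mask <- function(path, shape) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), max)
  if (!identical(dim(img), as.integer(shape))) {
    stop(sprintf("mask shape %d x %d does not match raster shape %d x %d",
                 dim(img)[1], dim(img)[2], shape[1], shape[2]))
  }
  m <- img > 0
  if (!any(m)) stop("empty mask: no in-region pixels")
  attr(m, "n_pixels") <- sum(m)
  m
}

check_mask <- function(mask, shape, what = "mask") {
  if (!is.logical(mask) || !identical(dim(mask), as.integer(shape))) {
    stop(sprintf("%s must be a logical matrix matching the %d x %d raster",
                 what, shape[1], shape[2]))
  }
  if (!any(mask)) stop(sprintf("empty %s: no in-region pixels", what))
  invisible(mask)
}
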