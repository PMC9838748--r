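#' Wavelength grid of a hyperspectral camera
#'
#' A `wavelength_grid` holds the ordered band-center wavelengths (nm) of a
#' spectral cube. Band centers must be finite and strictly increasing.
#'
#' @param band_centers Numeric vector of band-center wavelengths in nm.
#' @return An object of class `wavelength_grid` with fields `band_centers`
#'   and `count`.
#' @seealso [default_grid()]
#' @export
wavelength_grid <- function(band_centers) {
  band_centers <- as.numeric(band_centers)
  if (length(band_centers) < 1L || !all(is.finite(band_centers))) {
    stop("band_centers must be a non-empty finite numeric vector")
  }
  if (length(band_centers) > 1L && any(diff(band_centers) <= 0)) {
    stop("band_centers must be strictly increasing")
  }
  structure(
    list(band_centers = band_centers, count = length(band_centers)),
    class = "wavelength_grid"
  )
}

#' Default 128-band grid over 400-1000 nm
#'
#' Models a visible/NIR pushbroom camera with 128 spectral channels over
#' 400-1000 nm: band centers at `400 + k * (600/128)` nm for `k = 0..127`,
#' i.e. a 4.6875 nm spacing (4.69 nm when rounded to the precision such
#' cameras quote). Explicit band-center lists read from ENVI headers
#' override this default.
#'
#' @return A [wavelength_grid()] with 128 bands.
#' @export
#' @examples
#' g <- default_grid()
#' g$count            # 128
#' g$band_centers[1]  # 400
default_grid <- function() {
  wavelength_grid(400 + (0:127) * (600 / 128))
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> %d bands, %.4g-%.4g nm (mean spacing %.4g nm)\n",
    x$count, x$band_centers[1], x$band_centers[x$count],
    if (x$count > 1) mean(diff(x$band_centers)) else NA_real_
  ))
  invisible(x)
}

#' Default camera description
#'
#' Metadata record for the reference camera: 696 pixels per line, 128
#' channels, 12-bit dynamic range, 4.69 nm spectral resolution over
#' 400-1000 nm. Purely descriptive; the processing code reads dimensions
#' from the cubes themselves.
#'
#' @return A list of class `camera_spec`.
#' @export
default_camera_spec <- function() {
  structure(list(
    spatial_resolution = 696L,
    spectral_resolution_nm = 600 / 128,
    dynamic_range_bits = 12L,
    channels = 128L,
    dx = NA_real_, dy = NA_real_
  ), class = "camera_spec")
}
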