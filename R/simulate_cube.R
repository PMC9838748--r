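#' Scene layout for a synthetic acquisition
#'
#' Describes the spatial arrangement emulated by the cube generator: a
#' rectangular dye smear and a disjoint rectangular fragment of the 18%
#' gray panel, on a neutral slide background. Rectangles are 1-based
#' inclusive `c(first, last)` row/column ranges.
#'
#' @param rows,cols Scene dimensions in pixels.
#' @param dye_rows,dye_cols Dye-region rectangle.
#' @param panel_rows,panel_cols Gray-panel rectangle; must not overlap the
#'   dye region.
#' @return An object of class `scene_layout` with precomputed `dye_mask`
#'   and `panel_mask` logical matrices.
#' @export
scene_layout <- function(rows = 48, cols = 64,
                         dye_rows = c(9, 40), dye_cols = c(5, 36),
                         panel_rows = c(9, 40), panel_cols = c(45, 60)) {
  dye <- rect_mask(c(rows, cols), dye_rows, dye_cols)
  panel <- rect_mask(c(rows, cols), panel_rows, panel_cols)
  if (any(dye & panel)) stop("dye and panel regions must be disjoint")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 dye_mask = dye, panel_mask = panel),
            class = "scene_layout")
}

#' Illumination and sensor model
#'
#' Flat (or user-supplied) illumination spectrum, a scalar radiometric
#' gain, and additive zero-mean Gaussian DN noise. The study's acquisition
#' used incandescent light with flat spectral characteristics over
#' 400-1000 nm, which the all-ones default emulates.
#'
#' @param spectrum Per-band relative power (all > 0), or a single value
#'   recycled across bands at generation time.
#' @param gain DN per unit radiance (> 0). The default 4000 keeps a
#'   reflectance-1 target just inside the 12-bit range.
#' @param noise_sd Gaussian noise standard deviation in DN (>= 0).
#' @return An object of class `illumination_model`.
#' @export
illumination_model <- function(spectrum = 1, gain = 4000, noise_sd = 0) {
  if (any(!is.finite(spectrum)) || any(spectrum <= 0)) {
    stop("illumination spectrum values must all be > 0")
  }
  if (!is.finite(gain) || gain <= 0) stop("gain must be > 0")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(spectrum = as.numeric(spectrum), gain = gain,
                 noise_sd = noise_sd),
            class = "illumination_model")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a raw hyperspectral cube of one dye plus gray panel
#'
#' Forward model of the acquisition: in the dye region
#' `DN(m,n,k) = gain * spectrum(k) * rho_dye(k) + eps`, where `rho_dye` is
#' the entry's Gaussian reflectance model ([dye_model_reflectance()]); the
#' panel region uses a spectrally flat `rho = panel_reflectance` (default
#' 0.18) and the background slide `rho = background_reflectance` (default
#' 0.05). `eps` is i.i.d. Gaussian DN noise with sd `illum$noise_sd`,
#' reproducible from `seed`. DN are kept real-valued and clipped to the
#' 12-bit range `[0, 4095]` only from below (noise excursions under 0);
#' if any noiseless or noisy DN would exceed 4095 the generator stops with
#' a saturation error rather than truncating silently.
#'
#' @param entry A [dye_spec_entry()].
#' @param layout A [scene_layout()].
#' @param grid A [wavelength_grid()] with at least 3 bands.
#' @param illum An [illumination_model()].
#' @param seed Integer seed for the noise stream.
#' @param ru Reflectance per relative unit (default 1e-4).
#' @param panel_reflectance Panel reflectance fraction (default 0.18).
#' @param background_reflectance Slide background reflectance.
#' @return A list with `raw` (the DN [spectral_cube()]), `truth` (the
#'   noiseless ground-truth reflectance cube) and the masks of `layout`.
#' @export
generate_dye_cube <- function(entry, layout, grid = default_grid(),
                              illum = illumination_model(), seed = 1L,
                              ru = 1e-4, panel_reflectance = 0.18,
                              background_reflectance = 0.05) {
  if (grid$count < 3) stop("grid must have at least 3 bands")
  spectrum <- rep_len(illum$spectrum, grid$count)
  rho_dye <- dye_model_reflectance(entry, grid, ru = ru)

  nr <- layout$rows; nc <- layout$cols; nb <- grid$count
  rho <- array(background_reflectance, dim = c(nr, nc, nb))
  for (k in seq_len(nb)) {
    plane <- rho[, , k]
    plane[layout$dye_mask] <- rho_dye[k]
    plane[layout$panel_mask] <- panel_reflectance
    rho[, , k] <- plane
  }

  per_band_gain <- illum$gain * spectrum
  dn <- sweep(rho, 3, per_band_gain, `*`)
  if (max(dn) > 4095) {
    stop(sprintf(
      "saturation: noiseless DN reaches %.1f > 4095; lower gain or illumination",
      max(dn)))
  }
  if (illum$noise_sd > 0) {
    noise <- with_seed(seed, array(stats::rnorm(length(dn), 0, illum$noise_sd),
                                   dim = dim(dn)))
    dn <- dn + noise
    if (max(dn) > 4095) {
      stop(sprintf(
        "saturation: noisy DN reaches %.1f > 4095; lower gain or noise_sd",
        max(dn)))
    }
    dn[dn < 0] <- 0
  }

  list(raw = spectral_cube(dn, grid, "raw"),
       truth = spectral_cube(rho, grid, "reflectance"),
       dye_mask = layout$dye_mask,
       panel_mask = layout$panel_mask)
}
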