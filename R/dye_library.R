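#' Generative spectral model of one dye
#'
#' Each dye is modelled as a single broad Gaussian reflectance peak on a
#' flat baseline, expressed in relative units (r.u.): 1 r.u. = 1e-4
#' absolute reflectance, so the 18% gray panel corresponds to 1800 r.u.
#' The reflectance at wavelength lambda is
#' `1e-4 * (baseline + amplitude * exp(-(lambda - peak)^2 / (2 sigma^2)))`,
#' giving a spectrum maximum of `baseline + amplitude` r.u. at the peak.
#'
#' @param name Short machine name (e.g. `"dark_pink"`).
#' @param color_label Human-readable color.
#' @param peak_wavelength Peak wavelength in nm.
#' @param amplitude Peak height above baseline, in relative units (> 0).
#' @param width_sigma Gaussian sigma in nm (> 0).
#' @param baseline Flat baseline, relative units (>= 0);
#'   `baseline + amplitude` must not exceed 10000 r.u. (reflectance 1).
#' @return An object of class `dye_spec_entry`.
#' @export
dye_spec_entry <- function(name, color_label, peak_wavelength, amplitude,
                           width_sigma = 40, baseline = 0) {
  stopifnot(is.character(name), nchar(name) > 0)
  if (!is.finite(amplitude) || amplitude <= 0) stop("amplitude must be > 0")
  if (!is.finite(width_sigma) || width_sigma <= 0) stop("width_sigma must be > 0")
  if (!is.finite(baseline) || baseline < 0) stop("baseline must be >= 0")
  if (baseline + amplitude > 10000) {
    stop("baseline + amplitude exceeds 10000 r.u. (reflectance > 1)")
  }
  structure(list(
    name = name, color_label = color_label,
    peak_wavelength = peak_wavelength, amplitude = amplitude,
    width_sigma = width_sigma, baseline = baseline
  ), class = "dye_spec_entry")
}

#' @export
print.dye_spec_entry <- function(x, ...) {
  cat(sprintf("<dye_spec_entry> %s (%s): peak %.4g nm, %.4g r.u. (sigma %.3g nm, baseline %.3g r.u.)\n",
              x$name, x$color_label, x$peak_wavelength, x$amplitude,
              x$width_sigma, x$baseline))
  invisible(x)
}

#' Built-in seven-dye library
#'
#' The packaged library of the seven permanent-makeup/tattoo dyes analysed
#' in the study, in sample order: red, yellow, dark pink, black, light
#' pink, brown, white. The values printed in the study are encoded
#' verbatim: peak wavelengths 634 nm (red) and 732 nm (brown); maximum
#' reflectances 751 r.u. (red), 1304 r.u. (dark pink), 85 r.u. (black) and
#' 3222 r.u. (white). The remaining peak wavelengths and amplitudes are
#' not printed anywhere; the defaults below are fixed, documented
#' configuration values chosen inside the reported 634-732 nm peak range
#' and ordered by the reported ease-of-removal ranking reversed
#' (black < brown < red < dark pink < yellow < light pink < white).
#' All baselines default to 0 r.u., so `amplitude` is the spectrum maximum.
#'
#' @return A named list of 7 [dye_spec_entry()] objects.
#' @export
#' @examples
#' lib <- builtin_dye_library()
#' names(lib)
#' lib$red$peak_wavelength   # 634
#' lib$black$amplitude       # 85
builtin_dye_library <- function() {
  entries <- list(
    dye_spec_entry("red",        "Red",        634, 751),
    dye_spec_entry("yellow",     "Yellow",     668, 2000),
    dye_spec_entry("dark_pink",  "Dark pink",  652, 1304),
    dye_spec_entry("black",      "Black",      690, 85),
    dye_spec_entry("light_pink", "Light pink", 661, 2600),
    dye_spec_entry("brown",      "Brown",      732, 400),
    dye_spec_entry("white",      "White",      706, 3222)
  )
  names(entries) <- vapply(entries, `[[`, "", "name")
  entries
}

#' Read a dye library from YAML
#'
#' Expects a top-level `dyes:` sequence of maps with the fields of
#' [dye_spec_entry()] (`width_sigma` and `baseline` optional).
#'
#' @param path YAML file path.
#' @return Named list of [dye_spec_entry()] objects.
#' @export
dye_library_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$dyes) || length(y$dyes) == 0) stop("YAML has no 'dyes' entries")
  entries <- lapply(y$dyes, function(d) {
    dye_spec_entry(d$name, d$color_label %||% d$name,
                   d$peak_wavelength, d$amplitude,
                   d$width_sigma %||% 40, d$baseline %||% 0)
  })
  names(entries) <- vapply(entries, `[[`, "", "name")
  entries
}

#' @export
as.data.frame.dye_spec_entry <- function(x, ...) {
  data.frame(name = x$name, color_label = x$color_label,
             peak_wavelength = x$peak_wavelength, amplitude = x$amplitude,
             width_sigma = x$width_sigma, baseline = x$baseline,
             stringsAsFactors = FALSE)
}

#' Evaluate a dye's model reflectance spectrum
#'
#' Closed-form reflectance (fraction, not r.u.) of a library entry on a
#' wavelength grid.
#'
#' @param entry A [dye_spec_entry()].
#' @param grid A [wavelength_grid()].
#' @param ru Reflectance per relative unit (default 1e-4).
#' @return Numeric vector, one reflectance per band.
#' @export
dye_model_reflectance <- function(entry, grid, ru = 1e-4) {
  lam <- grid$band_centers
  ru * (entry$baseline +
          entry$amplitude * exp(-(lam - entry$peak_wavelength)^2 /
                                  (2 * entry$width_sigma^2)))
}
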