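test_that("panel self-calibration returns 18% in every band", {
  sim <- generate_dye_cube(builtin_dye_library()$red, small_layout(),
                           small_grid())
  refl <- calibrate(sim$raw, sim$panel_mask)
  for (k in seq_len(refl$grid$count)) {
    expect_equal(unique(refl$values[, , k][sim$panel_mask]), 0.18)
  }
})

test_that("calibration is invariant to global DN scale and illumination", {
  entry <- builtin_dye_library()$dark_pink
  lay <- small_layout(); g <- small_grid()
  a <- generate_dye_cube(entry, lay, g, illumination_model(gain = 2000))
  b <- generate_dye_cube(entry, lay, g, illumination_model(gain = 4000))
  ra <- calibrate(a$raw, a$panel_mask)
  rb <- calibrate(b$raw, b$panel_mask)
  expect_equal(ra$values, rb$values, tolerance = 1e-9)

  # arbitrary positive rescaling of an existing cube
  scaled <- spectral_cube(a$raw$values * 1.7, g, "raw")
  rs <- calibrate(scaled, a$panel_mask)
  expect_equal(rs$values, ra$values, tolerance = 1e-12)

  # non-flat illumination cancels band by band too
  spec <- seq(0.5, 1.5, length.out = g$count)
  c1 <- generate_dye_cube(entry, lay, g, illumination_model(spectrum = spec))
  c2 <- generate_dye_cube(entry, lay, g,
                          illumination_model(spectrum = 2 * spec, gain = 2000))
  expect_equal(calibrate(c1$raw, c1$panel_mask)$values,
               calibrate(c2$raw, c2$panel_mask)$values, tolerance = 1e-9)
})

test_that("noiseless calibration recovers the ground-truth reflectance", {
  for (entry in builtin_dye_library()) {
    sim <- generate_dye_cube(entry, small_layout(), small_grid())
    refl <- calibrate(sim$raw, sim$panel_mask)
    expect_equal(refl$values, sim$truth$values, tolerance = 1e-9)
    expect_true(min(refl$values) >= 0)
  }
})

test_that("double calibration and degenerate panels are refused", {
  sim <- generate_dye_cube(builtin_dye_library()$red, small_layout(),
                           small_grid())
  refl <- calibrate(sim$raw, sim$panel_mask)
  expect_error(calibrate(refl, sim$panel_mask), "twice")

  dead <- sim$raw$values
  dead[, , 3][sim$panel_mask] <- 0
  expect_error(calibrate(spectral_cube(dead, small_grid(), "raw"),
                         sim$panel_mask),
               "band 3")
})

test_that("ROI mean spectrum averages exactly", {
  g <- wavelength_grid(c(500, 600, 700))
  vals <- array(0, c(2, 2, 3))
  vals[1, 1, ] <- 0.1
  vals[2, 1, ] <- 0.3
  cube <- spectral_cube(vals, g, "reflectance")
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  s <- roi_mean_spectrum(cube, mask)
  expect_equal(s$values, rep(0.2, 3))
  expect_equal(s$n_pixels, 2)

  one <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_equal(roi_mean_spectrum(cube, one)$values, rep(0.1, 3))
  expect_error(roi_mean_spectrum(cube, matrix(FALSE, 2, 2)), "empty")
  expect_error(roi_mean_spectrum(generate_dye_cube(
    builtin_dye_library()$red, small_layout(), small_grid())$raw, mask),
    "reflectance")
})

test_that("peak refinement is exact on symmetric peaks and skipped at edges", {
  cfg <- calibration_config()
  lam <- seq(400, 1000, by = 50)
  tri <- pmax(0, 1 - abs(lam - 700) / 200)  # symmetric triangle on a band
  s <- structure(list(band_centers = lam, values = tri, n_pixels = 1),
                 class = "spectrum")
  expect_equal(peak_summary(s, cfg)$peak_wavelength_nm, 700)

  inc <- structure(list(band_centers = lam, values = seq_along(lam) / 13,
                        n_pixels = 1), class = "spectrum")
  p <- peak_summary(inc, cfg)
  expect_false(p$refined)
  expect_equal(p$peak_wavelength_nm, 1000)

  # ties break toward the lowest band
  flat <- structure(list(band_centers = lam,
                         values = rep(c(1, 1, 0), length.out = length(lam)),
                         n_pixels = 1), class = "spectrum")
  expect_equal(peak_summary(flat, cfg)$max_band_index, 1)
})

test_that("a constant baseline does not move the refined vertex", {
  cfg <- calibration_config()
  g <- small_grid(40)
  base <- exp(-(g$band_centers - 654)^2 / (2 * 45^2))
  s0 <- structure(list(band_centers = g$band_centers, values = base,
                       n_pixels = 1), class = "spectrum")
  s1 <- structure(list(band_centers = g$band_centers, values = base + 0.25,
                       n_pixels = 1), class = "spectrum")
  expect_equal(peak_summary(s0, cfg)$peak_wavelength_nm,
               peak_summary(s1, cfg)$peak_wavelength_nm, tolerance = 1e-9)
})

test_that("noiseless end-to-end runs recover all seven library parameters", {
  lay <- scene_layout()
  for (entry in builtin_dye_library()) {
    sim <- generate_dye_cube(entry, lay, default_grid())
    p <- analyze_dye(sim$raw, sim$dye_mask, sim$panel_mask,
                     dye_name = entry$name)
    expect_lt(abs(p$peak_wavelength_nm - entry$peak_wavelength), 0.5)
    expect_lt(abs(p$max_reflectance_ru - (entry$baseline + entry$amplitude)),
              0.5)
  }
})

test_that("amplitude error shrinks with ROI size under noise", {
  g <- small_grid(16)
  entry <- builtin_dye_library()$light_pink
  il <- illumination_model(noise_sd = 40)
  layouts <- list(
    small = scene_layout(20, 30, dye_rows = c(3, 6), dye_cols = c(3, 6),
                         panel_rows = c(3, 18), panel_cols = c(15, 28)),
    large = scene_layout(20, 30, dye_rows = c(3, 14), dye_cols = c(1, 12),
                         panel_rows = c(3, 18), panel_cols = c(15, 28)))
  err <- sapply(layouts, function(lay) {
    errs <- vapply(1:200, function(s) {
      sim <- generate_dye_cube(entry, lay, g, il, seed = s)
      p <- analyze_dye(sim$raw, sim$dye_mask, sim$panel_mask)
      abs(p$max_reflectance_ru - (entry$baseline + entry$amplitude))
    }, 0)
    mean(errs)
  })
  expect_lt(err[["large"]], err[["small"]])
})
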