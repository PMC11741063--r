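# A-scan analysis: peak detection, the ratio statistic, fallback, shadow
# substitution, foveal localization and per-eye measurement.

test_that("find_elm_peak: sub-pixel accuracy, tie rule, no-peak error", {
  sg <- oracle_sigma(0.6, 2.7)
  d <- seq(-70, -30, by = 0.89)
  v <- 1.3 * exp(-0.5 * ((d - (-50.3)) / sg)^2)
  attr(v, "depth_um") <- d
  pk <- find_elm_peak(v, c(-60, -40))
  expect_lt(abs(pk$depth_um - (-50.3)), 0.05)
  expect_lt(abs(pk$intensity - 1.3) / 1.3, 0.015)

  # two exactly equal maxima: the anterior one wins
  v2 <- rep(0, length(d))
  v2[10] <- 1; v2[32] <- 1
  attr(v2, "depth_um") <- d
  pk2 <- find_elm_peak(v2, range(d))
  expect_equal(pk2$index, 10)

  ramp <- seq_along(d) / length(d)
  attr(ramp, "depth_um") <- d
  expect_error(find_elm_peak(ramp, c(-60, -40)), "no local maximum")
})

test_that("find_subband_peak honours the gap criterion and PSF limit", {
  grid <- strip_grid()
  ph <- uniform_phenotype(0.8)
  prof <- render_ascan(two_band_model(psf_fwhm_um = 2.7), ph, flat_fovea(),
                       2, grid, speckle = FALSE)
  elm <- find_elm_peak(prof, c(-55, -45))
  sub <- find_subband_peak(prof, elm)
  expect_false(is.null(sub))
  expect_lt(abs(sub$offset_um - 4.9), 0.45)  # half an axial pixel

  # no sub-band (zero relative reflectivity): nothing to find
  solo <- render_ascan(two_band_model(), uniform_phenotype(0), flat_fovea(),
                       2, grid, speckle = FALSE)
  elm1 <- find_elm_peak(solo, c(-55, -45))
  expect_null(find_subband_peak(solo, elm1))

  # merged peaks at commercial resolution fail the gap criterion
  merged <- render_ascan(two_band_model(psf_fwhm_um = 6), ph, flat_fovea(),
                         2, grid, speckle = FALSE)
  elm6 <- find_elm_peak(merged, c(-55, -43))
  expect_null(find_subband_peak(merged, elm6))
})

test_that("measure_ratio: equality, scale invariance, fallback", {
  grid <- strip_grid()
  ph <- uniform_phenotype(0.8)
  prof <- render_ascan(outer_retina_model(), ph, flat_fovea(), 2, grid,
                       speckle = FALSE)
  m <- octsubband:::measure_profile(prof)
  expect_false(m$used_fallback)
  for (k in c(0.25, 3, 1700)) {     # ratio is scale-free
    mk <- octsubband:::measure_profile(prof * k)
    expect_equal(mk$ratio_pct, m$ratio_pct, tolerance = 1e-10)
  }
  elm <- find_elm_peak(prof, c(m$elm_depth_um - 2, m$elm_depth_um + 2))
  eq <- measure_ratio(prof, list(depth_um = elm$depth_um,
                                 intensity = elm$intensity, index = elm$index),
                      list(depth_um = elm$depth_um + 4.9,
                           intensity = elm$intensity, index = elm$index + 6,
                           offset_um = 4.9))
  expect_equal(eq$ratio_pct, 100)

  # fallback: sampled at ELM + 4.9 um, never above the found peak
  fb <- measure_ratio(prof, elm, NULL, fallback_offset_um = 4.9)
  expect_true(fb$used_fallback)
  expect_equal(fb$axial_offset_um, 4.9)
  sub <- find_subband_peak(prof, elm)
  expect_lte(fb$subband_peak_intensity, sub$intensity + 1e-12)
  expect_error(measure_ratio(prof, list(depth_um = -50, intensity = 0,
                                        index = 10), NULL),
               "non-positive")
})

test_that("fallback intensity <= found peak across reflectivities", {
  grid <- strip_grid()
  for (rel in c(0.3, 0.6, 0.9, 1.2)) {
    prof <- render_ascan(outer_retina_model(), uniform_phenotype(rel),
                         flat_fovea(), 1, grid, speckle = FALSE)
    m <- octsubband:::measure_profile(prof)
    d <- attr(prof, "depth_um")
    fbi <- approx(d, as.numeric(prof), xout = m$elm_depth_um + 4.9)$y
    expect_lte(fbi, m$subband_peak_intensity + 1e-9)
  }
})

test_that("shadow substitution picks the best neighbor, ties go nasal", {
  grid <- grid_spec(n_ascans_x = 100L, n_ascans_y = 1L)
  model <- outer_retina_model(speckle_shape = Inf)
  # shadow exactly at column 50 (x for col 50 with nx=100)
  x50 <- (50 - 50.5) * 12 / 1000
  ph <- uniform_phenotype(0.8, shadow_positions_mm = x50)
  vol <- render_volume(model, ph, flat_fovea(), grid, seed = 1,
                       speckle = FALSE)
  bs <- vol$data[, , 1]
  clean <- select_representative_ascan(bs, 20, grid)
  expect_identical(clean$column, 20L)
  expect_false(clean$shadow_substituted)

  sel <- select_representative_ascan(bs, 50, grid)
  expect_true(sel$shadow_substituted)
  expect_false(sel$unreliable)
  expect_true(abs(sel$column - 50) <= 5 && sel$column != 50)

  # equidistant equal-intensity candidates resolve nasally
  flat <- matrix(1, nrow = grid$n_depth_px, ncol = 100)
  flat[, 50] <- 0   # shadowed target, all neighbors identical
  tie <- select_representative_ascan(flat, 50, grid, nasal_dir = 1L)
  expect_identical(tie$column, 51L)
  tie2 <- select_representative_ascan(flat, 50, grid, nasal_dir = -1L)
  expect_identical(tie2$column, 49L)

  # every candidate shadowed: unreliable
  wide <- bs
  wide[, 45:55] <- wide[, 45:55] * 0.1
  bad <- select_representative_ascan(wide, 50, grid)
  expect_true(bad$unreliable)
})

test_that("locate_fovea finds designed centres and rejects flat volumes", {
  grid <- strip_grid(5L)
  model <- outer_retina_model(speckle_shape = Inf)
  ph <- uniform_phenotype(0.8)
  off <- foveal_geometry(center_x_mm = 0.6, elm_elevation_amp_um = 15)
  vol <- render_volume(model, ph, off, grid, seed = 2, speckle = FALSE)
  fc <- locate_fovea(vol)
  expect_lte(abs(fc$x_index - (250.5 + 0.6 * 1000 / 12)), 1)

  flat <- render_volume(model, ph, flat_fovea(), grid, seed = 2,
                        speckle = FALSE)
  expect_error(locate_fovea(flat), "ambiguous")
})

test_that("measure_eye measures six points and bounds-checks them", {
  grid <- strip_grid(3L)
  model <- outer_retina_model(speckle_shape = Inf)
  ph <- uniform_phenotype(0.8)
  vol <- render_volume(model, ph, foveal_geometry(), grid, seed = 3,
                       speckle = FALSE)
  m <- measure_eye(vol)
  expect_identical(nrow(m), 6L)
  expect_setequal(m$location, LOCATIONS)
  expect_true(all(m$status == "ok"))
  expect_true(all(m$ratio_pct > 0))

  # fovea 1.2 mm from the field edge: only the far 2-mm point drops out
  edge <- foveal_geometry(center_x_mm = 1.8, elm_elevation_amp_um = 15)
  vole <- render_volume(model, ph, edge, grid, seed = 3, speckle = FALSE)
  me <- measure_eye(vole)
  oob <- me$location[me$status == "out_of_bounds"]
  expect_identical(oob, "2N")   # OD: nasal = +x = toward that edge
  expect_identical(sum(me$status == "ok"), 5L)

  # global intensity scaling leaves every ratio unchanged
  vs <- vol; vs$data <- vs$data * 37
  ms <- measure_eye(vs)
  expect_equal(ms$ratio_pct, m$ratio_pct, tolerance = 1e-9)
})

test_that("measured offsets track per-eye truth within half a pixel", {
  grid <- strip_grid(3L)
  model <- outer_retina_model(speckle_shape = Inf)
  for (off in c(4.2, 4.9, 5.6)) {
    ph <- uniform_phenotype(0.85, offset_um = off)
    vol <- render_volume(model, ph, foveal_geometry(), grid, seed = 4,
                         speckle = FALSE)
    m <- measure_eye(vol)
    expect_true(all(abs(m$axial_offset_um - off) <= 0.445))
  }
})
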