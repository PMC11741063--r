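# Synthetic outer-retina simulator: rendering, speckle/fusion, cohort
# sampling and reflectivity calibration.

test_that("single-band noiseless A-scan is the band's Gaussian", {
  model <- outer_retina_model(
    bands = list(band_spec("ELM", -50, 1.0, 0)),
    speckle_shape = Inf, noise_floor = 0)
  ph <- uniform_phenotype(0)
  prof <- render_ascan(model, ph, flat_fovea(), 2, strip_grid(),
                       speckle = FALSE)
  d <- attr(prof, "depth_um")
  expect_true(all(prof >= 0))
  # peak height 1.0 at -50 um (oracle-derived parabolic bounds)
  pk <- find_elm_peak(prof, c(-60, -40))
  expect_lt(abs(pk$depth_um - (-50)), 0.05)
  expect_lt(abs(pk$intensity - 1.0), 0.015)
  # symmetry about the centre
  sg <- oracle_sigma(0, model$psf_fwhm_um)
  expect_equal(prof, exp(-0.5 * ((d - (-50)) / sg)^2),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("two-band render matches the dense-grid oracle", {
  sg27 <- oracle_sigma(0, 2.7)
  for (case in list(list(fwhm = 2.7, n_peaks = 2L),
                    list(fwhm = 6.0, n_peaks = 1L))) {
    model <- two_band_model(psf_fwhm_um = case$fwhm)
    ph <- uniform_phenotype(0.8)
    prof <- render_ascan(model, ph, flat_fovea(), 2, strip_grid(),
                         speckle = FALSE)
    d <- attr(prof, "depth_um")
    orc <- oracle_profile(c(-50, -45.1), c(1, 0.8),
                          rep(oracle_sigma(0, case$fwhm), 2))
    mx <- oracle_local_maxima(orc)
    expect_identical(mx$n, case$n_peaks)
    # coarse-grid samples agree with the oracle at shared points (<=1% peak)
    sel <- d >= min(orc$depth_um) & d <= max(orc$depth_um)
    ref <- approx(orc$depth_um, orc$intensity, xout = d[sel])$y
    expect_lt(max(abs(prof[sel] - ref)), 0.01 * max(ref))
    if (case$n_peaks == 2) {
      # peak heights exceed the bare amplitudes by the mutual tails
      expect_gt(mx$intensity[1], 1.0)
      expect_gt(mx$intensity[2], 0.8)
      expect_lt(mx$intensity[1], 1.01)
    }
  }
})

test_that("rendering is deterministic and nonnegative", {
  grid <- grid_spec(n_ascans_x = 60L, n_ascans_y = 4L)
  model <- outer_retina_model()
  ph <- uniform_phenotype(0.8, shadow_positions_mm = 0.1)
  v1 <- render_volume(model, ph, foveal_geometry(), grid, seed = 11)
  v2 <- render_volume(model, ph, foveal_geometry(), grid, seed = 11)
  v3 <- render_volume(model, ph, foveal_geometry(), grid, seed = 12)
  expect_identical(v1$data, v2$data)
  expect_false(identical(v1$data, v3$data))
  expect_true(all(v1$data >= 0))
})

test_that("volume fusion reduces speckle variance ~ 1/n", {
  grid <- grid_spec(n_ascans_x = 500L, n_ascans_y = 3L)
  fovea <- flat_fovea()
  ph <- uniform_phenotype(0)
  # fully developed speckle makes the variance contrast unambiguous
  m1 <- outer_retina_model(speckle_shape = 1, n_fused_volumes = 1L)
  m6 <- outer_retina_model(speckle_shape = 1, n_fused_volumes = 6L)
  elm_row <- which.min(abs(depth_axis_um_for_test(grid) + 50))
  v1 <- render_volume(m1, ph, fovea, grid, seed = 3)$data[elm_row, , ]
  v6 <- render_volume(m6, ph, fovea, grid, seed = 3)$data[elm_row, , ]
  ratio <- var(as.numeric(v1)) / var(as.numeric(v6))
  expect_gt(ratio, 6 * 0.8)
  expect_lt(ratio, 6 * 1.2)
})

test_that("foveal ELM elevation peaks at the designed centre", {
  grid <- strip_grid(3L)
  model <- outer_retina_model(speckle_shape = Inf)
  ph <- uniform_phenotype(0.8)
  fov <- foveal_geometry(elm_elevation_amp_um = 15)
  vol <- render_volume(model, ph, fov, grid, seed = 1, speckle = FALSE)
  fc <- locate_fovea(vol)
  expect_lte(abs(fc$x_index - 250.5), 1)
})

test_that("cohort sampling honours sizes, groups and degenerate sd", {
  des <- cohort_design(seed = 2)
  plan <- design_cohort(des, grid = strip_grid())
  expect_length(plan$phenotypes, 44)
  groups <- vapply(plan$phenotypes, `[[`, "", "age_group")
  expect_equal(as.numeric(table(factor(groups,
                                       c("young", "middle", "older")))),
               c(13, 18, 13))
  ages <- vapply(plan$phenotypes, `[[`, 0, "age_years")
  expect_true(all(ages[groups == "young"] >= 22 &
                    ages[groups == "young"] <= 38))
  expect_true(all(ages[groups == "older"] >= 62))

  plan1 <- design_cohort(cohort_design(1, 1, 1, seed = 3),
                         grid = strip_grid())
  expect_length(plan1$phenotypes, 3)
  expect_setequal(vapply(plan1$phenotypes, `[[`, "", "age_group"),
                  c("young", "middle", "older"))

  plan0 <- design_cohort(cohort_design(2, 1, 1, group_sd = 0, seed = 4),
                         grid = strip_grid())
  r1 <- plan0$phenotypes[[1]]$subband_rel_reflectivity
  r2 <- plan0$phenotypes[[2]]$subband_rel_reflectivity
  expect_identical(r1, r2)
  # reproducibility: same seed, same cohort
  planb <- design_cohort(cohort_design(2, 1, 1, group_sd = 0, seed = 4),
                         grid = strip_grid())
  expect_identical(plan0$phenotypes, planb$phenotypes)
})

test_that("per-eye offsets reproduce the designed median and IQR", {
  des <- cohort_design(seed = 9)
  set.seed(9)
  off <- octsubband:::draw_offsets(2000, des$offset_median_um,
                                   des$offset_iqr_um)
  expect_lt(abs(median(off) - 4.9), 0.1)
  q <- quantile(off, c(0.25, 0.75))
  expect_lt(abs(q[[1]] - 4.5), 0.1)
  expect_lt(abs(q[[2]] - 5.6), 0.15)
  expect_true(all(off > 3.9))  # shifted support: no unresolvable offsets
})

test_that("reflectivity calibration inverts the measurement map", {
  grid <- strip_grid()
  model <- outer_retina_model()
  # symmetry: equal designed and ELM amplitudes measure ~100% (the two
  # peaks sit at different grid phases, so parabolic height bias leaves a
  # ~1% residual asymmetry)
  f100 <- calibrate_reflectivity(100, model, grid)
  expect_lt(abs(f100 - 1.0), 0.02)
  # mutual tail + noise floor inflate the smaller peak more
  f77 <- calibrate_reflectivity(77, model, grid)
  expect_lt(f77, 0.77)
  # monotone forward map
  fr <- vapply(c(65, 77, 90), calibrate_reflectivity, numeric(1),
               model = model, grid = grid)
  expect_true(all(diff(fr) > 0))
  # round trip at 0.1-point tolerance
  ph <- uniform_phenotype(f77)
  prof <- render_ascan(model, ph, flat_fovea(), 2, grid, speckle = FALSE)
  expect_lt(abs(octsubband:::measure_profile(prof)$ratio_pct - 77), 0.1)
  expect_error(calibrate_reflectivity(149, model, grid), "unreachable")
})

test_that("out-of-field A-scans are rejected", {
  model <- outer_retina_model()
  expect_error(render_ascan(model, uniform_phenotype(0.8), flat_fovea(),
                            3.5, strip_grid()), "field of view")
})
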