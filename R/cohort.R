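# Cohort design and simulation.

#' Default designed measured-ratio targets (%) per age group and location
#'
#' Group-level targets of the measured sub-band/ELM peak-intensity ratio used
#' to parameterize the default simulated cohort: a healthy aging cohort in
#' which sub-band reflectivity rises from the young to the older group and is
#' highest at the 2 mm eccentricities.
#'
#' @return 3 x 6 numeric matrix (rows `young`, `middle`, `older`; columns
#'   [LOCATIONS]).
#' @export
default_ratio_targets <- function() {
  m <- rbind(
    young  = c(79, 76, 65, 68, 69, 75),
    middle = c(78, 75, 80, 76, 75, 81),
    older  = c(87, 86, 83, 78, 85, 92))
  colnames(m) <- LOCATIONS
  m
}

#' Cohort design
#'
#' Sample sizes, designed group-level sub-band reflectivities and the
#' between-eye spread of the simulated cohort. Defaults give a 44-eye cohort
#' (13 young / 18 middle / 13 older).
#'
#' @param n_young,n_middle,n_older Eyes per age group.
#' @param group_mean_rel_reflectivity Optional 3 x 6 matrix of intrinsic
#'   sub-band amplitude fractions (rows young/middle/older, columns
#'   [LOCATIONS]). If `NULL`, fractions are calibrated at simulation time so
#'   the noiseless measured ratios hit `ratio_targets_pct`.
#' @param ratio_targets_pct 3 x 6 matrix of measured-ratio targets (%);
#'   default [default_ratio_targets()].
#' @param group_sd Between-eye SD of the reflectivity fraction (same for all
#'   groups; 0 gives a degenerate design in which every eye sits exactly at
#'   its group mean). Default 0.12.
#' @param offset_median_um,offset_iqr_um Median and interquartile range of
#'   the per-eye ELM-to-sub-band offset; a log-normal is fitted to them.
#' @param calibration_psf_fwhm_um Axial PSF FWHM (um) under which the
#'   ratio targets are defined (the reference high-resolution instrument).
#'   Reflectivities are intrinsic eye properties: they are calibrated under
#'   this PSF even when volumes are rendered at a different (e.g. a
#'   commercial 6-um) resolution.
#' @param shadow_rate Mean number of vessel-shadow columns per eye (Poisson).
#' @param p_dm Probability an eye belongs to a diabetic subject (healthy
#'   macula).
#' @param seed Integer seed; the full cohort is reproducible from it.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_young = 13L, n_middle = 18L, n_older = 13L,
                          group_mean_rel_reflectivity = NULL,
                          ratio_targets_pct = default_ratio_targets(),
                          group_sd = 0.12,
                          offset_median_um = 4.9,
                          offset_iqr_um = c(4.5, 5.6),
                          calibration_psf_fwhm_um = 2.7,
                          shadow_rate = 1.2, p_dm = 0.2, seed = 1L) {
  stopifnot(n_young >= 1, n_middle >= 1, n_older >= 1, group_sd >= 0,
            offset_median_um > 0, length(offset_iqr_um) == 2)
  d <- list(n_young = as.integer(n_young), n_middle = as.integer(n_middle),
            n_older = as.integer(n_older),
            group_mean_rel_reflectivity = group_mean_rel_reflectivity,
            ratio_targets_pct = ratio_targets_pct,
            group_sd = group_sd, offset_median_um = offset_median_um,
            offset_iqr_um = offset_iqr_um,
            calibration_psf_fwhm_um = calibration_psf_fwhm_um,
            shadow_rate = shadow_rate,
            p_dm = p_dm, seed = as.integer(seed))
  class(d) <- "cohort_design"
  d
}

AGE_RANGES <- list(young = c(22L, 38L), middle = c(42L, 60L),
                   older = c(62L, 90L))

#' Invert the measurement map: intrinsic fraction for a target measured ratio
#'
#' The measured peak ratio differs slightly from the intrinsic amplitude
#' fraction because each band's PSF tail inflates the other's peak (the
#' smaller peak proportionally more). This finds, by monotone 1-D root
#' search on noiseless renders, the intrinsic sub-band amplitude fraction
#' whose measured ratio equals `target_pct` within 0.1 percentage points.
#'
#' @param target_pct Target measured ratio in percent, in (0, 150].
#' @param model An [outer_retina_model()].
#' @param grid A [grid_spec()].
#' @param x_mm Eccentricity at which the calibration A-scan is rendered
#'   (outside the foveola; default 2 mm).
#' @return Intrinsic amplitude fraction in \[0, 1.5\].
#' @export
calibrate_reflectivity <- function(target_pct, model, grid = grid_spec(),
                                   x_mm = 2) {
  stopifnot(target_pct > 0, target_pct <= 150)
  flat_fovea <- foveal_geometry(elm_elevation_amp_um = 0,
                                subband_suppression_radius_mm = 0)
  forward <- function(frac) {
    rel <- stats::setNames(rep(frac, 6), LOCATIONS)
    ph <- eye_phenotype("cal", 50, "OD", rel,
                        elm_subband_offset_um = model$elm_subband_offset_um)
    prof <- render_ascan(model, ph, flat_fovea, x_mm, grid, speckle = FALSE)
    m <- measure_profile(prof, grid, model$elm_subband_offset_um)
    m$ratio_pct
  }
  hi <- forward(1.5)
  if (hi < target_pct - 0.1)
    stop(sprintf("target %.1f%% unreachable (max measurable %.1f%%)",
                 target_pct, hi))
  lo <- forward(1e-4)
  if (lo > target_pct)
    stop(sprintf("target %.1f%% below the noise-floor ratio %.1f%%",
                 target_pct, lo))
  stats::uniroot(function(f) forward(f) - target_pct,
                 interval = c(1e-4, 1.5), tol = 1e-6)$root
}

# Calibrated 3x6 fraction matrix for a design (computed once per run).
calibrated_fractions <- function(design, model, grid) {
  if (!is.null(design$group_mean_rel_reflectivity))
    return(design$group_mean_rel_reflectivity)
  cal_model <- model
  if (!is.null(design$calibration_psf_fwhm_um))
    cal_model$psf_fwhm_um <- design$calibration_psf_fwhm_um
  targets <- design$ratio_targets_pct
  out <- targets * NA_real_
  for (g in rownames(targets)) for (l in colnames(targets))
    out[g, l] <- calibrate_reflectivity(targets[g, l], cal_model, grid)
  out
}

rtrunc_norm <- function(n, mean, sd, lo = 0, hi = 1.5) {
  if (sd == 0) return(rep_len(as.numeric(mean), n))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# Shifted log-normal matching the median and BOTH quartiles exactly:
# offset = shift + LN(meanlog, sdlog). The printed quartiles are
# right-skewed (q3 - med > med - q1), which a 2-parameter log-normal cannot
# reproduce; the shift solves (med - a)^2 = (q3 - a)(q1 - a).
offset_params <- function(median_um, iqr_um) {
  q1 <- iqr_um[1]; q3 <- iqr_um[2]
  denom <- q1 + q3 - 2 * median_um
  a <- if (abs(denom) > 1e-9) (q1 * q3 - median_um^2) / denom else -Inf
  if (!is.finite(a) || a >= q1 || a < 0) {
    # (near-)symmetric quartiles: plain log-normal on the geometric spread
    return(list(shift = 0, meanlog = log(median_um),
                sdlog = log(q3 / q1) / (2 * stats::qnorm(0.75))))
  }
  list(shift = a, meanlog = log(median_um - a),
       sdlog = log((q3 - a) / (median_um - a)) / stats::qnorm(0.75))
}

# Offsets are truncated to max_um (default 8): the sub-band is a myoid
# feature and must stay well anterior to the ellipsoid zone (14 um
# posterior to the ELM in the band model); the un-truncated upper tail of
# the fitted log-normal would occasionally place it inside the EZ.
draw_offsets <- function(n, median_um, iqr_um, max_um = 8) {
  p <- offset_params(median_um, iqr_um)
  hi <- stats::plnorm(max_um - p$shift, p$meanlog, p$sdlog)
  u <- stats::runif(n, 0, hi)
  p$shift + stats::qlnorm(u, meanlog = p$meanlog, sdlog = p$sdlog)
}

#' Draw the phenotypes of a simulated cohort (no rendering)
#'
#' Ages are uniform within each group's range, lateralities balanced,
#' per-eye per-location reflectivity fractions are truncated-normal draws
#' around the calibrated group means, and the per-eye ELM-to-sub-band offset
#' is log-normal with the designed median and IQR. Per-eye rendering seeds
#' are drawn here so that volumes are reproducible eye by eye.
#'
#' @param design A [cohort_design()].
#' @param model,grid Passed to the reflectivity calibration.
#' @return List with `phenotypes` (list of [eye_phenotype()]), `eye_seeds`
#'   (integer vector) and `fractions` (the calibrated 3 x 6 group means).
#' @export
design_cohort <- function(design, model = outer_retina_model(),
                          grid = grid_spec()) {
  frac <- calibrated_fractions(design, model, grid)
  set.seed(design$seed)
  ns <- c(young = design$n_young, middle = design$n_middle,
          older = design$n_older)
  phenotypes <- list()
  i <- 0L
  for (g in names(ns)) {
    rng <- AGE_RANGES[[g]]
    for (k in seq_len(ns[[g]])) {
      i <- i + 1L
      age <- sample(seq(rng[1], rng[2]), 1L)
      lat <- sample(c("OD", "OS"), 1L)
      rel <- rtrunc_norm(6, frac[g, ], design$group_sd)
      names(rel) <- LOCATIONS
      off <- draw_offsets(1, design$offset_median_um, design$offset_iqr_um)
      nsh <- stats::rpois(1, design$shadow_rate)
      shadows <- if (nsh > 0) stats::runif(nsh, -2.8, 2.8) else numeric(0)
      phenotypes[[i]] <- eye_phenotype(
        eye_id = sprintf("eye%03d", i), age_years = age, laterality = lat,
        subband_rel_reflectivity = rel, elm_subband_offset_um = off,
        has_dm = stats::runif(1) < design$p_dm,
        shadow_positions_mm = shadows)
    }
  }
  eye_seeds <- sample.int(.Machine$integer.max - 1L, length(phenotypes))
  list(phenotypes = phenotypes, eye_seeds = eye_seeds, fractions = frac)
}

#' Simulate a full cohort of eyes with rendered volumes
#'
#' @inheritParams design_cohort
#' @param fovea A [foveal_geometry()] shared by all eyes.
#' @param speckle Logical; `FALSE` renders noiselessly.
#' @return List of eyes, each a list with `phenotype` and `volume`. For
#'   large grids prefer streaming with [measure_cohort()], which renders one
#'   eye at a time.
#' @export
simulate_cohort <- function(design, model = outer_retina_model(),
                            fovea = foveal_geometry(), grid = grid_spec(),
                            speckle = TRUE) {
  plan <- design_cohort(design, model, grid)
  mapply(function(ph, sd) {
    list(phenotype = ph,
         volume = render_volume(model, ph, fovea, grid, seed = sd,
                                speckle = speckle))
  }, plan$phenotypes, plan$eye_seeds, SIMPLIFY = FALSE)
}

cohort_manifest <- function(phenotypes, eye_seeds = NA_integer_) {
  data.frame(
    eye_id = vapply(phenotypes, `[[`, "", "eye_id"),
    age_years = vapply(phenotypes, `[[`, 0, "age_years"),
    age_group = vapply(phenotypes, `[[`, "", "age_group"),
    laterality = vapply(phenotypes, `[[`, "", "laterality"),
    has_dm = vapply(phenotypes, `[[`, TRUE, "has_dm"),
    elm_subband_offset_um =
      vapply(phenotypes, `[[`, 0, "elm_subband_offset_um"),
    n_shadows = vapply(phenotypes,
                       function(p) length(p$shadow_positions_mm), 0L),
    seed = eye_seeds,
    stringsAsFactors = FALSE)
}
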