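#' Sampling grid of a flattened outer-retina OCT volume
#'
#' Describes the voxel grid of a raster-scanned OCT volume after flattening:
#' axial (depth) sampling in micrometres per pixel and isotropic transverse
#' A-scan spacing. Defaults correspond to a high-resolution spectral-domain
#' prototype acquiring 500 x 500 A-scans over a 6 x 6 mm field with 0.89 um
#' axial and 12 um transverse pixels.
#'
#' @param axial_pixel_um Axial pixel size, micrometres per pixel.
#' @param transverse_pixel_um Transverse A-scan spacing, micrometres.
#' @param n_ascans_x Number of A-scans per B-scan (fast axis).
#' @param n_ascans_y Number of B-scans (slow axis).
#' @param n_depth_px Number of axial samples; must span the outer retina
#'   plus margin (>= 220 at the default axial pixel size).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(axial_pixel_um = 0.89, transverse_pixel_um = 12,
                      n_ascans_x = 500L, n_ascans_y = 500L,
                      n_depth_px = 220L) {
  stopifnot(axial_pixel_um > 0, transverse_pixel_um > 0,
            n_ascans_x >= 1, n_ascans_y >= 1, n_depth_px >= 1)
  g <- list(axial_pixel_um = axial_pixel_um,
            transverse_pixel_um = transverse_pixel_um,
            n_ascans_x = as.integer(n_ascans_x),
            n_ascans_y = as.integer(n_ascans_y),
            n_depth_px = as.integer(n_depth_px))
  class(g) <- "grid_spec"
  g
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d A-scans (%g um), %d depth px (%g um/px)\n",
              x$n_ascans_x, x$n_ascans_y, x$transverse_pixel_um,
              x$n_depth_px, x$axial_pixel_um))
  invisible(x)
}

# Depth row (1-based) at which Bruch's membrane sits in a flattened volume.
# Leaves ~44 um posterior margin at default sampling.
brm_row_for <- function(grid) grid$n_depth_px - 50L

# Depth in um relative to Bruch's membrane for each row (negative = anterior).
depth_axis_um <- function(grid) {
  (seq_len(grid$n_depth_px) - brm_row_for(grid)) * grid$axial_pixel_um
}

#' One reflective outer-retinal band
#'
#' A band is modelled as a Gaussian reflectivity profile in depth, centred at
#' a signed axial offset from Bruch's membrane (negative = anterior, the
#' convention of a volume flattened to Bruch's).
#'
#' @param name Band label; one of `"ELM"`, `"SUBBAND"`, `"EZ"`, `"RPE_BRM"`.
#' @param center_depth_um Band centre relative to Bruch's membrane (um,
#'   anterior offsets negative).
#' @param amplitude Linear reflectivity amplitude (arbitrary units, >= 0).
#' @param intrinsic_width_um Gaussian sigma of the band before PSF blur (um).
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(name, center_depth_um, amplitude, intrinsic_width_um) {
  name <- match.arg(name, c("ELM", "SUBBAND", "EZ", "RPE_BRM"))
  stopifnot(amplitude >= 0, intrinsic_width_um >= 0)
  b <- list(name = name, center_depth_um = center_depth_um,
            amplitude = amplitude, intrinsic_width_um = intrinsic_width_um)
  class(b) <- "band_spec"
  b
}

default_bands <- function() {
  # Centres: ELM ~50 um anterior to Bruch's; the myoid sub-band 4.9 um
  # posterior to the ELM (set by the model's offset, the value here is a
  # placeholder overwritten at render time); EZ leaves a hyporeflective
  # inner-ellipsoid gap posterior to the sub-band; RPE-Bruch's complex is
  # the thick posterior reference.
  list(
    band_spec("ELM",     -50.0, 1.0, 0.6),
    band_spec("SUBBAND", -45.1, 1.0, 0.6),
    band_spec("EZ",      -36.0, 1.4, 1.2),
    band_spec("RPE_BRM",   0.0, 1.8, 4.0)
  )
}

#' Parametric model of the outer retina as seen by OCT
#'
#' Bundles the band geometry with the imaging-system parameters: the axial
#' point-spread-function FWHM, the ELM-to-sub-band axial offset, the number
#' of fused volumes and the multiplicative speckle statistics.
#'
#' Speckle is modelled as i.i.d. per-pixel unit-mean gamma noise per virtual
#' acquisition; fusion averages `n_fused_volumes` independent realizations.
#' The default `speckle_shape` of 64 reproduces the smoothness of fused
#' high-resolution linear-scale A-scan profiles (fused peak CV ~ 4.5%);
#' `speckle_shape = 1` gives fully developed speckle, `Inf` disables noise.
#'
#' @param bands List of [band_spec()] objects.
#' @param psf_fwhm_um Axial PSF full width at half maximum (um), default 2.7.
#' @param elm_subband_offset_um Axial distance from the ELM peak to the
#'   sub-band peak (um), default 4.9 (the cohort median).
#' @param n_fused_volumes Number of averaged speckle realizations, default 6.
#' @param speckle_shape Gamma shape of per-acquisition multiplicative
#'   speckle; `Inf` for noiseless rendering.
#' @param noise_floor Additive background intensity (a.u.).
#' @return An object of class `outer_retina_model`.
#' @export
outer_retina_model <- function(bands = default_bands(), psf_fwhm_um = 2.7,
                               elm_subband_offset_um = 4.9,
                               n_fused_volumes = 6L, speckle_shape = 64,
                               noise_floor = 0.02) {
  stopifnot(psf_fwhm_um > 0, elm_subband_offset_um > 0,
            n_fused_volumes >= 1, speckle_shape > 0, noise_floor >= 0)
  nm <- vapply(bands, function(b) b$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate band names in model")
  m <- list(bands = bands, psf_fwhm_um = psf_fwhm_um,
            elm_subband_offset_um = elm_subband_offset_um,
            n_fused_volumes = as.integer(n_fused_volumes),
            speckle_shape = speckle_shape, noise_floor = noise_floor)
  class(m) <- "outer_retina_model"
  m
}

model_band <- function(model, name) {
  for (b in model$bands) if (b$name == name) return(b)
  NULL
}

# FWHM of a Gaussian = 2*sqrt(2*log(2)) * sigma
FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))  # 1/2.3548...

#' Foveal geometry of a simulated eye
#'
#' The ELM bows anteriorly at the foveal centre (a Gaussian elevation bump)
#' and the myoid sub-band thins to absence in the foveola; both features are
#' what the analysis uses to locate the fovea and why no measurement is taken
#' at the centre itself.
#'
#' @param center_x_mm,center_y_mm Foveal centre in field coordinates (mm,
#'   0 = field centre).
#' @param elm_elevation_amp_um Peak anterior elevation of the ELM (um).
#' @param elevation_sigma_mm Gaussian sigma of the elevation bump (mm).
#' @param subband_suppression_radius_mm Radius inside which the sub-band
#'   amplitude tapers smoothly to zero (mm).
#' @return An object of class `foveal_geometry`.
#' @export
foveal_geometry <- function(center_x_mm = 0, center_y_mm = 0,
                            elm_elevation_amp_um = 15,
                            elevation_sigma_mm = 0.35,
                            subband_suppression_radius_mm = 0.25) {
  stopifnot(elevation_sigma_mm > 0, subband_suppression_radius_mm >= 0)
  f <- list(center_x_mm = center_x_mm, center_y_mm = center_y_mm,
            elm_elevation_amp_um = elm_elevation_amp_um,
            elevation_sigma_mm = elevation_sigma_mm,
            subband_suppression_radius_mm = subband_suppression_radius_mm)
  class(f) <- "foveal_geometry"
  f
}

#' Measurement locations along the horizontal meridian
#'
#' Nasal (N) and temporal (T) eccentricities at 0.5, 1 and 2 mm from the
#' foveal centre, the six locations at which the sub-band is assessed.
#' @format Character vector of length 6.
#' @export
LOCATIONS <- c("2N", "1N", "0.5N", "0.5T", "1T", "2T")

# Signed internal x (mm, positive = nasal) of each location for a given eye.
# For a right eye (OD) the internal x axis runs temporal -> nasal with
# increasing column index; for OS the axis is mirrored.
location_x_mm <- function(laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  ecc <- c(`2N` = 2, `1N` = 1, `0.5N` = 0.5,
           `0.5T` = -0.5, `1T` = -1, `2T` = -2)
  if (laterality == "OS") ecc <- -ecc
  ecc
}

age_group_of <- function(age_years) {
  stopifnot(all(age_years >= 21))
  cut(age_years, breaks = c(20, 40, 60, Inf),
      labels = c("young", "middle", "older"))
}

#' One simulated eye
#'
#' @param eye_id Identifier label.
#' @param age_years Subject age in years (>= 21).
#' @param laterality `"OD"` (right) or `"OS"` (left).
#' @param subband_rel_reflectivity Named numeric vector over [LOCATIONS]:
#'   sub-band amplitude as a fraction of the ELM amplitude, in \[0, 1.5\].
#' @param elm_subband_offset_um Per-eye ELM-to-sub-band offset (um).
#' @param has_dm Diabetes-mellitus flag (no retinopathy modelled).
#' @param shadow_positions_mm Eccentricities (mm, signed internal x) of
#'   vessel-shadow columns.
#' @return An object of class `eye_phenotype`.
#' @export
eye_phenotype <- function(eye_id, age_years, laterality = "OD",
                          subband_rel_reflectivity,
                          elm_subband_offset_um = 4.9,
                          has_dm = FALSE, shadow_positions_mm = numeric(0)) {
  laterality <- match.arg(laterality, c("OD", "OS"))
  stopifnot(setequal(names(subband_rel_reflectivity), LOCATIONS),
            all(subband_rel_reflectivity >= 0),
            all(subband_rel_reflectivity <= 1.5),
            elm_subband_offset_um > 0)
  p <- list(eye_id = as.character(eye_id), age_years = age_years,
            age_group = as.character(age_group_of(age_years)),
            laterality = laterality,
            subband_rel_reflectivity =
              subband_rel_reflectivity[LOCATIONS],
            elm_subband_offset_um = elm_subband_offset_um,
            has_dm = isTRUE(has_dm),
            shadow_positions_mm = shadow_positions_mm)
  class(p) <- "eye_phenotype"
  p
}

#' @export
print.eye_phenotype <- function(x, ...) {
  cat(sprintf("<eye_phenotype> %s: age %s (%s), %s, offset %.2f um\n",
              x$eye_id, x$age_years, x$age_group, x$laterality,
              x$elm_subband_offset_um))
  invisible(x)
}
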