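# Rendering of synthetic outer-retina A-scans and volumes.
#
# An A-scan is a sum of Gaussian bands on the axial grid; the axial PSF adds
# in quadrature to each band's intrinsic width. Speckle is multiplicative
# unit-mean gamma noise per pixel, averaged over n_fused_volumes virtual
# acquisitions. The mean of n i.i.d. Gamma(s, scale 1/s) draws is exactly
# Gamma(n*s, scale 1/(n*s)), so fusion is drawn in one pass.

effective_sigma_um <- function(band, model) {
  sqrt(band$intrinsic_width_um^2 + (model$psf_fwhm_um * FWHM_TO_SIGMA)^2)
}

fovea_elevation_um <- function(fovea, x_mm, y_mm) {
  r2 <- (x_mm - fovea$center_x_mm)^2 + (y_mm - fovea$center_y_mm)^2
  fovea$elm_elevation_amp_um * exp(-r2 / (2 * fovea$elevation_sigma_mm^2))
}

# Smooth 0->1 taper of the sub-band amplitude inside the foveola.
fovea_suppression <- function(fovea, x_mm, y_mm) {
  r0 <- fovea$subband_suppression_radius_mm
  if (r0 <= 0) return(rep(1, length(x_mm)))
  r <- sqrt((x_mm - fovea$center_x_mm)^2 + (y_mm - fovea$center_y_mm)^2)
  t <- pmin(pmax(r / r0, 0), 1)
  t * t * (3 - 2 * t)  # smoothstep
}

# Per-eye sub-band relative reflectivity as a function of signed x (mm):
# linear interpolation between the six designed locations, constant beyond.
subband_rel_at <- function(phenotype, x_mm) {
  pos <- location_x_mm(phenotype$laterality)
  ord <- order(pos)
  stats::approx(pos[ord], phenotype$subband_rel_reflectivity[ord],
                xout = x_mm, rule = 2)$y
}

# x coordinate (signed mm, positive = nasal for OD) of each column index.
column_x_mm <- function(grid) {
  (seq_len(grid$n_ascans_x) - (grid$n_ascans_x + 1) / 2) *
    grid$transverse_pixel_um / 1000
}

column_y_mm <- function(grid) {
  (seq_len(grid$n_ascans_y) - (grid$n_ascans_y + 1) / 2) *
    grid$transverse_pixel_um / 1000
}

# Clean (noiseless, floor included) B-scan at slow-axis position y_mm:
# matrix n_depth_px x n_ascans_x. brm_shift_um optionally displaces the
# whole band stack posteriorly per column (un-flattened rendering).
render_clean_bscan <- function(model, phenotype, fovea, grid, y_mm,
                               brm_shift_um = NULL) {
  x_mm <- column_x_mm(grid)
  nx <- grid$n_ascans_x
  if (is.null(brm_shift_um)) brm_shift_um <- numeric(nx)
  stopifnot(length(brm_shift_um) == nx)
  d <- depth_axis_um(grid)
  elev <- fovea_elevation_um(fovea, x_mm, y_mm)
  rel <- subband_rel_at(phenotype, x_mm) * fovea_suppression(fovea, x_mm, y_mm)

  img <- matrix(model$noise_floor, nrow = grid$n_depth_px, ncol = nx)
  elm <- model_band(model, "ELM")
  for (b in model$bands) {
    center <- rep(b$center_depth_um, nx)
    amp <- rep(b$amplitude, nx)
    if (b$name %in% c("ELM", "SUBBAND", "EZ")) center <- center - elev
    if (b$name == "SUBBAND") {
      if (!is.null(elm)) {
        center <- elm$center_depth_um - elev +
          phenotype$elm_subband_offset_um
      }
      amp <- (if (is.null(elm)) b$amplitude else elm$amplitude) * rel
    }
    center <- center + brm_shift_um
    sg <- effective_sigma_um(b, model)
    # outer difference depth - center, vectorized over columns
    z <- (matrix(d, nrow = length(d), ncol = nx) -
            matrix(center, nrow = length(d), ncol = nx, byrow = TRUE)) / sg
    img <- img + matrix(amp, nrow = length(d), ncol = nx, byrow = TRUE) *
      exp(-0.5 * z * z)
  }
  img
}

apply_speckle <- function(x, model) {
  if (!is.finite(model$speckle_shape)) return(x)
  k <- model$n_fused_volumes * model$speckle_shape
  x * stats::rgamma(length(x), shape = k, rate = k)
}

#' Render one synthetic A-scan
#'
#' Evaluates the band model at a single transverse position: the sum of
#' Gaussian bands (PSF-broadened, sub-band placed at the eye's ELM offset and
#' scaled by its local relative reflectivity and foveolar suppression), plus
#' the additive noise floor, corrupted by fused multiplicative speckle.
#' Uses the current RNG state; seed with [set.seed()] for reproducibility.
#'
#' @param model An [outer_retina_model()].
#' @param phenotype An [eye_phenotype()].
#' @param fovea A [foveal_geometry()].
#' @param x_mm Signed transverse position (mm, positive = nasal internally).
#' @param grid A [grid_spec()].
#' @param y_mm Slow-axis position (mm), default the foveal centre row.
#' @param speckle Logical; `FALSE` renders noiselessly.
#' @return Numeric vector of linear intensities (length `grid$n_depth_px`),
#'   with the depth axis (um relative to Bruch's) in attribute `"depth_um"`.
#' @export
render_ascan <- function(model, phenotype, fovea, x_mm, grid,
                         y_mm = fovea$center_y_mm, speckle = TRUE) {
  half <- grid$n_ascans_x * grid$transverse_pixel_um / 2000
  if (abs(x_mm) > half)
    stop(sprintf("x = %g mm outside the +/-%g mm field of view", x_mm, half))
  d <- depth_axis_um(grid)
  elev <- fovea_elevation_um(fovea, x_mm, y_mm)
  rel <- subband_rel_at(phenotype, x_mm) *
    fovea_suppression(fovea, x_mm, y_mm)
  prof <- rep(model$noise_floor, grid$n_depth_px)
  elm <- model_band(model, "ELM")
  for (b in model$bands) {
    center <- b$center_depth_um
    amp <- b$amplitude
    if (b$name %in% c("ELM", "SUBBAND", "EZ")) center <- center - elev
    if (b$name == "SUBBAND") {
      if (!is.null(elm))
        center <- elm$center_depth_um - elev + phenotype$elm_subband_offset_um
      amp <- (if (is.null(elm)) b$amplitude else elm$amplitude) * rel
    }
    sg <- effective_sigma_um(b, model)
    prof <- prof + amp * exp(-0.5 * ((d - center) / sg)^2)
  }
  if (speckle) prof <- apply_speckle(prof, model)
  attr(prof, "depth_um") <- d
  prof
}

#' Render a synthetic flattened OCT volume
#'
#' Renders every A-scan of the raster, applies fused speckle, and attenuates
#' vessel-shadow columns. The volume is flattened by construction (Bruch's
#' membrane at a fixed row) unless a displacement map is supplied.
#'
#' @inheritParams render_ascan
#' @param seed Integer seed; a fixed seed yields a bit-identical volume.
#' @param brm_displacement_px Optional numeric vector (per column) or matrix
#'   (columns x B-scans) of posterior Bruch's displacements in pixels, used
#'   to exercise segmentation/flattening on un-flattened data.
#' @param shadow_attenuation Multiplicative attenuation applied to whole
#'   A-scans within `shadow_halfwidth_um` of a shadow position.
#' @param shadow_halfwidth_um Lateral half-width of a vessel shadow (um).
#' @return An object of class `oct_volume`: list with `data` (array depth x
#'   x x y, linear intensity), `grid`, `brm_row`, and truth annotations.
#' @export
render_volume <- function(model, phenotype, fovea, grid, seed = 1L,
                          speckle = TRUE, brm_displacement_px = NULL,
                          shadow_attenuation = 0.3,
                          shadow_halfwidth_um = 18) {
  set.seed(as.integer(seed))
  nx <- grid$n_ascans_x; ny <- grid$n_ascans_y
  if (!is.null(brm_displacement_px)) {
    brm_displacement_px <- if (is.matrix(brm_displacement_px)) {
      stopifnot(nrow(brm_displacement_px) == nx,
                ncol(brm_displacement_px) == ny)
      brm_displacement_px
    } else {
      matrix(rep(brm_displacement_px, ny), nrow = nx)
    }
  }
  x_mm <- column_x_mm(grid)
  y_mm <- column_y_mm(grid)
  vol <- array(0, dim = c(grid$n_depth_px, nx, ny))
  for (j in seq_len(ny)) {
    shift <- if (is.null(brm_displacement_px)) NULL else
      brm_displacement_px[, j] * grid$axial_pixel_um
    bs <- render_clean_bscan(model, phenotype, fovea, grid, y_mm[j],
                             brm_shift_um = shift)
    if (speckle) bs <- apply_speckle(bs, model)
    vol[, , j] <- bs
  }
  if (length(phenotype$shadow_positions_mm)) {
    for (sx in phenotype$shadow_positions_mm) {
      hit <- abs(x_mm - sx) * 1000 <= shadow_halfwidth_um
      if (any(hit)) vol[, hit, ] <- vol[, hit, ] * shadow_attenuation
    }
  }
  v <- list(data = vol, grid = grid, brm_row = brm_row_for(grid),
            phenotype = phenotype, fovea_truth = fovea,
            flattened = is.null(brm_displacement_px), seed = as.integer(seed))
  class(v) <- "oct_volume"
  v
}

#' @export
print.oct_volume <- function(x, ...) {
  cat(sprintf(
    "<oct_volume> %d x %d A-scans x %d depth px, BrM row %d, %sflattened\n",
    x$grid$n_ascans_x, x$grid$n_ascans_y, x$grid$n_depth_px, x$brm_row,
    if (x$flattened) "" else "not "))
  invisible(x)
}

# Extract the B-scan (depth x columns matrix) at slow-axis index j.
volume_bscan <- function(volume, j) volume$data[, , j]
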