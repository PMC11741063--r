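# Shared small fixtures, built in code.

# Two-band model (ELM + sub-band only, zero intrinsic widths, no floor):
# the minimal resolvability testbed. The sub-band amplitude is set by the
# phenotype's relative reflectivity at render time.
two_band_model <- function(psf_fwhm_um = 2.7, offset_um = 4.9,
                           speckle_shape = Inf) {
  outer_retina_model(
    bands = list(band_spec("ELM", -50, 1.0, 0),
                 band_spec("SUBBAND", -50 + offset_um, 1.0, 0)),
    psf_fwhm_um = psf_fwhm_um, elm_subband_offset_um = offset_um,
    speckle_shape = speckle_shape, noise_floor = 0)
}

flat_fovea <- function() {
  foveal_geometry(elm_elevation_amp_um = 0,
                  subband_suppression_radius_mm = 0)
}

uniform_phenotype <- function(rel = 0.8, eye_id = "t1", age = 50,
                              laterality = "OD", offset_um = 4.9, ...) {
  eye_phenotype(eye_id, age, laterality,
                stats::setNames(rep(rel, 6), LOCATIONS),
                elm_subband_offset_um = offset_um, ...)
}

# Small grid: full +/-3 mm transverse extent, few B-scans.
strip_grid <- function(ny = 5L) grid_spec(n_ascans_y = ny)

depth_axis_um_for_test <- function(grid) octsubband:::depth_axis_um(grid)
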