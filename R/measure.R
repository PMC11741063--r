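# A-scan peak-intensity ratiometry.
#
# The statistic of interest is the sub-band/ELM peak intensity ratio (%),
# measured on linear-scale A-scans: the highest local maximum in the ELM
# window, the most prominent gap-separated local maximum 2-10 um posterior
# for the sub-band, 3-point parabolic sub-pixel refinement of both, and a
# fixed-offset fallback (sample at ELM + 4.9 um) when no distinct sub-band
# peak exists. Intensities are never noise-corrected.

# Indices of strict local maxima of a numeric vector (first sample of a
# plateau wins, i.e. the anterior one on a depth axis).
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[v[i] > v[i - 1] & v[i] >= v[i + 1]]
}

# 3-point parabolic refinement around index i: sub-pixel shift (in pixels,
# in [-0.5, 0.5]) and interpolated peak height.
parabolic_refine <- function(v, i) {
  if (i <= 1 || i >= length(v)) return(list(shift = 0, height = v[i]))
  denom <- v[i - 1] - 2 * v[i] + v[i + 1]
  if (denom == 0) return(list(shift = 0, height = v[i]))
  shift <- 0.5 * (v[i - 1] - v[i + 1]) / denom
  shift <- max(min(shift, 0.5), -0.5)
  list(shift = shift, height = v[i] - 0.25 * (v[i - 1] - v[i + 1]) * shift)
}

ascan_depth_axis <- function(ascan, grid = NULL) {
  d <- attr(ascan, "depth_um")
  if (is.null(d)) {
    if (is.null(grid)) stop("A-scan carries no depth axis and no grid given")
    d <- depth_axis_um(grid)
  }
  d
}

#' Locate the ELM peak on an A-scan
#'
#' Returns the highest local maximum inside an expected depth window, with
#' sub-pixel centre and height from 3-point parabolic interpolation. When
#' two maxima tie in height the anterior one is returned.
#'
#' @param ascan Numeric A-scan (linear intensity); depth axis taken from its
#'   `"depth_um"` attribute or from `grid`.
#' @param expected_window_um Length-2 depth window (um relative to Bruch's)
#'   searched for the peak.
#' @param grid Optional [grid_spec()] supplying the depth axis.
#' @return List with `depth_um`, `intensity` and `index`.
#' @export
find_elm_peak <- function(ascan, expected_window_um, grid = NULL) {
  d <- ascan_depth_axis(ascan, grid)
  v <- as.numeric(ascan)
  in_win <- which(d >= expected_window_um[1] & d <= expected_window_um[2])
  if (!length(in_win)) stop("expected window outside the A-scan depth range")
  cand <- intersect(local_maxima(v), in_win)
  if (!length(cand)) stop("no local maximum in the expected ELM window")
  i <- cand[which.max(v[cand])]  # which.max -> first (anterior) on ties
  p <- parabolic_refine(v, i)
  px <- if (length(d) > 1) d[2] - d[1] else 1
  list(depth_um = d[i] + p$shift * px, intensity = p$height, index = i)
}

#' Locate the sub-band peak posterior to the ELM
#'
#' Searches `search_window_um` posterior to the ELM peak for the most
#' prominent local maximum that is separated from the ELM by a hyporeflective
#' gap: a local minimum strictly below both peak heights must lie between
#' them. Absence of such a peak is a valid outcome (`NULL`), the quantitative
#' counterpart of a not-visible sub-band.
#'
#' @inheritParams find_elm_peak
#' @param elm Result of [find_elm_peak()].
#' @param search_window_um Offsets posterior to the ELM searched (um),
#'   default `c(2, 10)`: covers the population IQR of the offset with margin
#'   while excluding the ellipsoid zone.
#' @param min_prominence Minimum prominence (candidate height minus the gap
#'   minimum) as a fraction of the ELM peak intensity, default 0.1. The
#'   hyporeflective gap must be appreciably darker than both peaks;
#'   otherwise few-percent speckle dips on a merged band (e.g. at a 6-um
#'   commercial PSF) would masquerade as a resolved sub-band.
#' @return List with `depth_um`, `intensity`, `index`, `offset_um`, or
#'   `NULL` when no gap-separated peak exists.
#' @export
find_subband_peak <- function(ascan, elm, search_window_um = c(2, 10),
                              grid = NULL, min_prominence = 0.1) {
  d <- ascan_depth_axis(ascan, grid)
  v <- as.numeric(ascan)
  lo <- elm$depth_um + search_window_um[1]
  hi <- elm$depth_um + search_window_um[2]
  cand <- local_maxima(v)
  cand <- cand[d[cand] >= lo & d[cand] <= hi & cand > elm$index]
  if (!length(cand)) return(NULL)
  prom <- vapply(cand, function(i) {
    gap_min <- min(v[(elm$index + 1):(i - 1)])
    if (gap_min >= v[i] || gap_min >= v[elm$index]) return(NA_real_)
    p <- v[i] - gap_min
    if (p < min_prominence * elm$intensity) return(NA_real_)
    p
  }, numeric(1))
  if (all(is.na(prom))) return(NULL)
  i <- cand[which.max(prom)]
  p <- parabolic_refine(v, i)
  px <- if (length(d) > 1) d[2] - d[1] else 1
  depth <- d[i] + p$shift * px
  list(depth_um = depth, intensity = p$height, index = i,
       offset_um = depth - elm$depth_um)
}

#' Compute the sub-band/ELM peak-intensity ratio for one A-scan
#'
#' `ratio = 100 * I_subband / I_ELM`, all in linear scale. If no distinct
#' sub-band peak was found, the sub-band intensity is sampled (linear
#' interpolation) at the population-median offset posterior to the ELM and
#' `used_fallback` is set.
#'
#' @inheritParams find_subband_peak
#' @param subband Result of [find_subband_peak()], possibly `NULL`.
#' @param fallback_offset_um Offset used when no peak was found (um),
#'   default 4.9 (the cohort median when visible).
#' @return List with fields `elm_peak_intensity`, `subband_peak_intensity`,
#'   `ratio_pct`, `axial_offset_um`, `used_fallback`.
#' @export
measure_ratio <- function(ascan, elm, subband = NULL,
                          fallback_offset_um = 4.9, grid = NULL) {
  if (elm$intensity <= 0) stop("non-positive ELM peak intensity")
  if (!is.null(subband)) {
    isub <- subband$intensity
    off <- subband$offset_um
    fb <- FALSE
  } else {
    d <- ascan_depth_axis(ascan, grid)
    isub <- stats::approx(d, as.numeric(ascan),
                          xout = elm$depth_um + fallback_offset_um)$y
    off <- fallback_offset_um
    fb <- TRUE
  }
  list(elm_peak_intensity = elm$intensity, subband_peak_intensity = isub,
       ratio_pct = 100 * isub / elm$intensity, axial_offset_um = off,
       used_fallback = fb)
}

# Row of the anterior-most local maximum at or above `frac` of the A-scan
# maximum: a robust rough localization of the ELM (the most anterior bright
# outer-retinal band). NA when no such maximum exists.
rough_elm_row <- function(v, frac = 0.35) {
  mx <- local_maxima(v)
  mx <- mx[v[mx] >= frac * max(v)]
  if (!length(mx)) NA_integer_ else mx[1]
}

# Full single-A-scan measurement: rough ELM localization, refined ELM peak
# in a tight window, sub-band search, ratio with fallback.
measure_profile <- function(ascan, grid = NULL, fallback_offset_um = 4.9,
                            search_window_um = c(2, 10)) {
  d <- ascan_depth_axis(ascan, grid)
  attr(ascan, "depth_um") <- d
  r <- rough_elm_row(as.numeric(ascan))
  if (is.na(r)) stop("no band detectable on A-scan")
  px <- d[2] - d[1]
  elm <- find_elm_peak(ascan, c(d[r] - 2.5 * px, d[r] + 2.5 * px))
  sub <- find_subband_peak(ascan, elm, search_window_um)
  m <- measure_ratio(ascan, elm, sub, fallback_offset_um)
  m$elm_depth_um <- elm$depth_um
  m
}

#' Pick a representative A-scan, avoiding vessel shadows
#'
#' If the target column's mean outer-retina intensity falls below
#' `shadow_frac` of the B-scan median (a shadow), the column within +/-
#' `search_halfwidth` A-scans maximizing that mean is used instead; ties go
#' to the nearer column and, when equidistant, to the nasal one.
#'
#' @param bscan Depth x columns intensity matrix.
#' @param target_column Column index of the nominal distance point.
#' @param grid A [grid_spec()] (for the outer-retina depth window).
#' @param search_halfwidth Columns searched on each side (default 5,
#'   i.e. +/-60 um laterally at 12 um spacing).
#' @param shadow_frac Shadow threshold as a fraction of the B-scan median
#'   outer-retina intensity (default 0.5).
#' @param nasal_dir +1 if the nasal direction is toward larger column
#'   indices, -1 otherwise.
#' @return List with `column`, `shadow_substituted`, `unreliable` (all 11
#'   candidate columns shadowed).
#' @export
select_representative_ascan <- function(bscan, target_column, grid,
                                        search_halfwidth = 5L,
                                        shadow_frac = 0.5, nasal_dir = 1L) {
  stopifnot(target_column >= 1, target_column <= ncol(bscan))
  d <- depth_axis_um(grid)
  outer <- d >= -70 & d <= 10  # ELM .. just posterior to Bruch's
  target_column <- as.integer(target_column)
  colmean <- colMeans(bscan[outer, , drop = FALSE])
  thr <- shadow_frac * stats::median(colmean)
  if (colmean[target_column] >= thr)
    return(list(column = target_column, shadow_substituted = FALSE,
                unreliable = FALSE))
  cand <- setdiff(
    max(1L, target_column - as.integer(search_halfwidth)):
      min(ncol(bscan), target_column + as.integer(search_halfwidth)),
    target_column)
  if (!length(cand) || max(colmean[cand]) < thr)
    return(list(column = target_column, shadow_substituted = FALSE,
                unreliable = TRUE))
  best <- max(colmean[cand])
  tied <- cand[colmean[cand] == best]
  dist <- abs(tied - target_column)
  tied <- tied[dist == min(dist)]
  col <- if (length(tied) > 1)
    tied[which.max(nasal_dir * (tied - target_column))] else tied[1]
  list(column = col, shadow_substituted = TRUE, unreliable = FALSE)
}

#' Locate the foveal centre from the ELM elevation
#'
#' Estimates the ELM depth on every A-scan (the anterior-most bright band),
#' smooths the ELM-to-Bruch's distance map with a 5 x 5 moving average and
#' returns the A-scan maximizing it.
#'
#' @param volume A flattened [render_volume()] result.
#' @return List of class `foveal_center` with `x_index`, `y_index`,
#'   `elm_height_um`.
#' @export
locate_fovea <- function(volume) {
  grid <- volume$grid
  nx <- grid$n_ascans_x; ny <- grid$n_ascans_y
  elm_row <- matrix(NA_real_, nx, ny)
  for (j in seq_len(ny)) {
    bs <- volume_bscan(volume, j)
    elm_row[, j] <- vapply(seq_len(nx), function(i) {
      r <- rough_elm_row(bs[, i])
      if (is.na(r)) return(NA_real_)
      # sub-pixel ELM depth, else quantization flattens the elevation map
      r + parabolic_refine(bs[, i], r)$shift
    }, numeric(1))
  }
  if (mean(is.na(elm_row)) > 0.5)
    stop("no ELM detectable on more than half of the A-scans")
  height <- (volume$brm_row - elm_row) * grid$axial_pixel_um
  height[is.na(height)] <- stats::median(height, na.rm = TRUE)
  sm <- moving_average_2d(height, 5L)
  if (max(sm) - stats::median(sm) < 1.5 * grid$axial_pixel_um)
    stop("no distinct ELM elevation: foveal centre is ambiguous")
  idx <- arrayInd(which.max(sm), dim(sm))
  out <- list(x_index = idx[1], y_index = idx[2],
              elm_height_um = sm[idx[1], idx[2]])
  class(out) <- "foveal_center"
  out
}

# k x k moving average with edge renormalization.
moving_average_2d <- function(m, k = 5L) {
  h <- k %/% 2
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (di in -h:h) for (dj in -h:h) {
    ri <- max(1, 1 - di):min(nr, nr - di)
    rj <- max(1, 1 - dj):min(nc, nc - dj)
    out[ri, rj] <- out[ri, rj] + m[ri + di, rj + dj]
    cnt[ri, rj] <- cnt[ri, rj] + 1
  }
  out / cnt
}

#' Measure the six distance points of one eye
#'
#' Measures the sub-band/ELM ratio on the horizontal B-scan through the
#' foveal centre at 0.5, 1 and 2 mm nasally and temporally, after shadow
#' substitution. A distance point falling outside the field of view yields a
#' row with `status = "out_of_bounds"` and NA measurements; other locations
#' are unaffected.
#'
#' @param volume A flattened [render_volume()] result.
#' @param fovea_center Result of [locate_fovea()] (located if `NULL`).
#' @param fallback_offset_um Fallback offset for [measure_ratio()].
#' @return A data frame with one row per location: the measurement fields,
#'   shadow/fallback/reliability flags and the measured column index.
#' @export
measure_eye <- function(volume, fovea_center = NULL,
                        fallback_offset_um = 4.9) {
  if (is.null(fovea_center)) fovea_center <- locate_fovea(volume)
  grid <- volume$grid
  ph <- volume$phenotype
  lat <- if (is.null(ph)) "OD" else ph$laterality
  eye_id <- if (is.null(ph)) "eye" else ph$eye_id
  nasal_dir <- if (lat == "OD") 1L else -1L
  bs <- volume_bscan(volume, fovea_center$y_index)
  locs <- location_x_mm(lat)
  rows <- lapply(names(locs), function(loc) {
    target <- fovea_center$x_index +
      as.integer(round(locs[[loc]] * 1000 / grid$transverse_pixel_um))
    na_row <- data.frame(
      eye_id = eye_id, location = loc, ascan_index = NA_integer_,
      elm_peak_intensity = NA_real_, subband_peak_intensity = NA_real_,
      ratio_pct = NA_real_, axial_offset_um = NA_real_,
      used_fallback = NA, shadow_substituted = NA, unreliable = NA,
      status = "out_of_bounds", stringsAsFactors = FALSE)
    if (target < 1 || target > grid$n_ascans_x) return(na_row)
    sel <- select_representative_ascan(bs, target, grid,
                                       nasal_dir = nasal_dir)
    prof <- bs[, sel$column]
    attr(prof, "depth_um") <- depth_axis_um(grid)
    m <- measure_profile(prof, fallback_offset_um = fallback_offset_um)
    data.frame(
      eye_id = eye_id, location = loc, ascan_index = sel$column,
      elm_peak_intensity = m$elm_peak_intensity,
      subband_peak_intensity = m$subband_peak_intensity,
      ratio_pct = m$ratio_pct, axial_offset_um = m$axial_offset_um,
      used_fallback = m$used_fallback,
      shadow_substituted = sel$shadow_substituted,
      unreliable = sel$unreliable, status = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
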