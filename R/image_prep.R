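# Display/grading preparation: Bruch's membrane segmentation and
# flattening, iterative histogram auto-contrast that saturates the outer
# retinal bands, and axial stretching. Display always uses a linear scale.

#' Segment Bruch's membrane
#'
#' Intensity-based substitute for learned layer segmentation, valid on
#' synthetic volumes: per A-scan, the deepest local maximum whose height
#' reaches `prominence_frac` of the A-scan maximum (the RPE-Bruch's
#' complex), smoothed by a running median over 5 A-scans. A-scans with no
#' qualifying band are marked invalid and filled from their neighbors.
#'
#' @param volume An [render_volume()] result (possibly un-flattened).
#' @param prominence_frac Height threshold as a fraction of the A-scan max.
#' @return Numeric matrix (columns x B-scans) of Bruch's row indices.
#' @export
segment_brm <- function(volume, prominence_frac = 0.3) {
  grid <- volume$grid
  nx <- grid$n_ascans_x; ny <- grid$n_ascans_y
  depth <- matrix(NA_real_, nx, ny)
  kern <- rep(1 / 5, 5)  # axial pre-smoothing suppresses speckle maxima
  for (j in seq_len(ny)) {
    bs <- volume_bscan(volume, j)
    depth[, j] <- vapply(seq_len(nx), function(i) {
      v <- bs[, i]
      if (max(v) > 0) {
        sm <- as.numeric(stats::filter(v, kern, sides = 2))
        v <- ifelse(is.na(sm), v, sm)
      }
      mx <- local_maxima(v)
      mx <- mx[v[mx] >= prominence_frac * max(v)]
      if (!length(mx)) NA_real_ else as.numeric(mx[length(mx)])
    }, numeric(1))
  }
  if (all(is.na(depth)))
    stop("no Bruch's membrane detectable on any A-scan")
  for (j in seq_len(ny)) {
    col <- depth[, j]
    if (anyNA(col)) {
      ok <- which(!is.na(col))
      if (!length(ok)) {
        col[] <- stats::median(depth, na.rm = TRUE)
      } else {
        col <- stats::approx(ok, col[ok], xout = seq_len(nx), rule = 2)$y
      }
    }
    depth[, j] <- stats::runmed(col, 5, endrule = "keep")
  }
  depth
}

#' Flatten a volume to Bruch's membrane
#'
#' Shifts every A-scan (linear interpolation for sub-pixel shifts) so that
#' Bruch's membrane sits at the volume's fixed reference row; samples shifted
#' in from outside the depth window are padded with `pad_value`. The applied
#' shifts are retained in attribute `"applied_shift_px"` for coordinate
#' mapping.
#'
#' @param volume An [render_volume()] result.
#' @param depth_map Bruch's row indices from [segment_brm()].
#' @param target_row Destination row for Bruch's (default the volume's
#'   `brm_row`).
#' @param pad_value Fill intensity for out-of-window samples (default the
#'   per-A-scan minimum, approximating the noise floor).
#' @return A flattened `oct_volume`.
#' @export
flatten_to_brm <- function(volume, depth_map, target_row = volume$brm_row,
                           pad_value = NULL) {
  grid <- volume$grid
  nx <- grid$n_ascans_x; ny <- grid$n_ascans_y; nz <- grid$n_depth_px
  stopifnot(nrow(depth_map) == nx, ncol(depth_map) == ny)
  out <- volume
  shift <- depth_map - target_row  # positive: BrM too deep, shift up
  rows <- seq_len(nz)
  for (j in seq_len(ny)) {
    bs <- volume_bscan(volume, j)
    for (i in seq_len(nx)) {
      s <- shift[i, j]
      if (s == 0) next
      pad <- if (is.null(pad_value)) min(bs[, i]) else pad_value
      out$data[, i, j] <- stats::approx(rows, bs[, i], xout = rows + s,
                                        rule = 1)$y
      miss <- is.na(out$data[, i, j])
      if (any(miss)) out$data[miss, i, j] <- pad
    }
  }
  out$flattened <- TRUE
  attr(out, "applied_shift_px") <- shift
  out
}

#' Iterative histogram auto-contrast
#'
#' Linear display windowing in the style of the classic ImageJ "Auto"
#' brightness/contrast heuristic: each press computes a 256-bin histogram of
#' the currently windowed data and moves the window limits to the lowest and
#' highest bins whose counts exceed `total_pixels / saturation_divisor`.
#' Repeated presses narrow the window monotonically; pixels at or above the
#' final maximum (here, the bright outer retinal bands) saturate at 1.
#'
#' @param image Numeric matrix of linear intensities (depth x columns).
#' @param saturation_divisor Histogram count threshold divisor (default
#'   5000, the classic heuristic).
#' @param n_auto_presses Number of times the auto function is applied
#'   (>= 1); grading uses a fixed press count across eyes.
#' @return An object of class `display_image`: list with `pixels` (values
#'   in \[0, 1\]), `window` (display min/max in input units) and
#'   `stretch_factor` (1 until [axial_stretch()] is applied).
#' @export
auto_contrast <- function(image, saturation_divisor = 5000,
                          n_auto_presses = 1L) {
  stopifnot(n_auto_presses >= 1)
  v <- as.numeric(image)
  if (max(v) == min(v)) stop("constant image: no contrast to stretch")
  win <- range(v)
  threshold <- length(v) / saturation_divisor
  for (press in seq_len(n_auto_presses)) {
    inside <- v[v >= win[1] & v <= win[2]]
    if (max(inside) == min(inside)) break
    edges <- seq(win[1], win[2], length.out = 257)
    counts <- tabulate(findInterval(inside, edges,
                                    rightmost.closed = TRUE,
                                    all.inside = TRUE), nbins = 256)
    lo <- which(counts > threshold)
    if (!length(lo)) break
    new_win <- c(edges[min(lo)], edges[max(lo) + 1])
    if (identical(new_win, win)) break
    win <- new_win
  }
  px <- (image - win[1]) / (win[2] - win[1])
  px[px < 0] <- 0; px[px > 1] <- 1
  out <- list(pixels = px, window = win, stretch_factor = 1)
  class(out) <- "display_image"
  out
}

#' Stretch an image along the depth axis
#'
#' Resamples depth only (transverse untouched), emulating the axially
#' stretched aspect ratio used for grading so that the few-micrometre
#' ELM-to-sub-band gap spans many display pixels.
#'
#' @param image Numeric matrix (depth x columns) or a `display_image`.
#' @param factor Stretch factor >= 1.
#' @param method `"nearest"` (row replication for integer factors) or
#'   `"linear"`.
#' @return Same type as the input, with `factor * nrow` rows.
#' @export
axial_stretch <- function(image, factor, method = c("nearest", "linear")) {
  method <- match.arg(method)
  if (factor < 1) stop("stretch factor must be >= 1")
  if (inherits(image, "display_image")) {
    image$pixels <- axial_stretch(image$pixels, factor, method)
    image$stretch_factor <- image$stretch_factor * factor
    return(image)
  }
  nr <- nrow(image)
  n_out <- as.integer(round(nr * factor))
  src <- if (method == "nearest") {
    pmin(pmax(ceiling(seq_len(n_out) / factor), 1L), nr)
  } else NULL
  if (method == "nearest") return(image[src, , drop = FALSE])
  xout <- seq(1, nr, length.out = n_out)
  apply(image, 2, function(col) stats::approx(seq_len(nr), col,
                                              xout = xout)$y)
}

#' Prepare a grading panel from a B-scan
#'
#' Flags the full grading display chain on one B-scan: auto-contrast with a
#' fixed press count followed by axial stretching (linear scale throughout).
#'
#' @param bscan Depth x columns linear-intensity matrix.
#' @param n_auto_presses Presses of [auto_contrast()] (default 2, enough to
#'   saturate the outer bands when they occupy a small pixel fraction).
#' @param stretch Axial stretch factor (default 4).
#' @param saturation_divisor Passed to [auto_contrast()].
#' @return A `display_image`.
#' @export
prepare_grading_image <- function(bscan, n_auto_presses = 2L, stretch = 4,
                                  saturation_divisor = 5000) {
  di <- auto_contrast(bscan, saturation_divisor, n_auto_presses)
  axial_stretch(di, stretch)
}
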