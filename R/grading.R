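# B-scan visibility grading, emulated: an automated visibility proxy on the
# measurement neighborhood, simulated imperfect graders, majority voting
# over three calls, and adjudication of "cannot determine" by the proxy.

GRADE_LEVELS <- c("visible", "not_visible", "cannot_determine")

#' Automated visibility proxy for one distance point
#'
#' Declares the sub-band visible when a distinct, gap-separated sub-band
#' peak exists with a peak ratio at or above `visibility_threshold` on the
#' representative A-scan AND on at least half of the +/-`halfwidth`
#' neighboring A-scans (graders judge B-scan continuity, not a single
#' A-scan). A measurement flagged unreliable (all candidate A-scans
#' shadowed) grades as `cannot_determine`.
#'
#' @param measurement One row of [measure_eye()] output (list or 1-row
#'   data frame).
#' @param bscan Depth x columns linear-intensity matrix the measurement was
#'   made on.
#' @param grid A [grid_spec()].
#' @param visibility_threshold Ratio threshold in percent (default 60; the
#'   observed correspondence between reader visibility and the A-scan
#'   ratio).
#' @param halfwidth Neighborhood half-width in A-scans (default 5).
#' @param fallback_offset_um Fallback offset for neighbor measurements.
#' @return One of `"visible"`, `"not_visible"`, `"cannot_determine"`.
#' @export
auto_grade <- function(measurement, bscan, grid, visibility_threshold = 60,
                       halfwidth = 5L, fallback_offset_um = 4.9) {
  m <- as.list(measurement)
  if (isTRUE(m$unreliable) || identical(m$status, "out_of_bounds"))
    return("cannot_determine")
  if (isTRUE(m$used_fallback) || m$ratio_pct < visibility_threshold)
    return("not_visible")
  col <- m$ascan_index
  nb <- setdiff(max(1L, col - halfwidth):min(ncol(bscan), col + halfwidth),
                col)
  d <- depth_axis_um(grid)
  ok <- vapply(nb, function(i) {
    prof <- bscan[, i]
    attr(prof, "depth_um") <- d
    mm <- tryCatch(measure_profile(prof,
                                   fallback_offset_um = fallback_offset_um),
                   error = function(e) NULL)
    !is.null(mm) && !mm$used_fallback &&
      mm$ratio_pct >= visibility_threshold
  }, logical(1))
  if (sum(ok) >= length(nb) / 2) "visible" else "not_visible"
}

#' Simulate one human grader's call
#'
#' Emits `cannot_determine` with probability `p_undetermined`; otherwise a
#' Bernoulli draw reproducing the underlying call with the grader's
#' sensitivity (on truly visible sub-bands) or specificity (on truly
#' not-visible ones). Uses the current RNG state.
#'
#' @param truth `"visible"` or `"not_visible"` (the proxy's call).
#' @param sensitivity,specificity Probabilities of agreeing with a visible /
#'   not-visible truth.
#' @param p_undetermined Probability of declining to call.
#' @return A grade category.
#' @export
simulate_grader <- function(truth, sensitivity = 0.85, specificity = 0.85,
                            p_undetermined = 0.05) {
  stopifnot(truth %in% c("visible", "not_visible"),
            sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            p_undetermined >= 0, p_undetermined <= 1)
  if (stats::runif(1) < p_undetermined) return("cannot_determine")
  p_agree <- if (truth == "visible") sensitivity else specificity
  if (stats::runif(1) < p_agree) truth
  else setdiff(c("visible", "not_visible"), truth)
}

#' Default panel of three simulated graders
#'
#' Sensitivity/specificity/undetermined rates chosen so that pairwise
#' agreement lands in a fair-to-moderate kappa range; configuration, not a
#' claim about any particular human panel.
#' @return List of three parameter lists.
#' @export
default_graders <- function() {
  list(list(sensitivity = 0.85, specificity = 0.85, p_undetermined = 0.05),
       list(sensitivity = 0.90, specificity = 0.80, p_undetermined = 0.03),
       list(sensitivity = 0.80, specificity = 0.90, p_undetermined = 0.10))
}

#' Majority vote over three grader calls
#'
#' Two or more concordant `visible`/`not_visible` calls decide the final
#' grading. Otherwise (ties broken by `cannot_determine` calls) the
#' automated proxy adjudicates: visible iff a distinct sub-band peak was
#' found and the measured ratio reaches the threshold.
#'
#' @param calls Character vector of exactly 3 grade categories.
#' @param measurement The location's measurement row (for adjudication).
#' @param visibility_threshold Ratio threshold in percent.
#' @return List with `call` (`"visible"`/`"not_visible"`) and `adjudicated`.
#' @export
majority_vote <- function(calls, measurement, visibility_threshold = 60) {
  stopifnot(length(calls) == 3, all(calls %in% GRADE_LEVELS))
  n_vis <- sum(calls == "visible")
  n_not <- sum(calls == "not_visible")
  if (n_vis >= 2) return(list(call = "visible", adjudicated = FALSE))
  if (n_not >= 2) return(list(call = "not_visible", adjudicated = FALSE))
  m <- as.list(measurement)
  vis <- !isTRUE(m$used_fallback) && !is.na(m$ratio_pct) &&
    m$ratio_pct >= visibility_threshold
  list(call = if (vis) "visible" else "not_visible", adjudicated = TRUE)
}

#' Grade every measured location of a cohort
#'
#' Runs the automated proxy as ground truth for the simulated grader panel,
#' then the majority vote with proxy adjudication. Seed the RNG before
#' calling for reproducible panels.
#'
#' @param measurements Measurement table ([measure_eye()] rows, all eyes).
#' @param bscans Named list (by `eye_id`) of the B-scans measured, for the
#'   neighborhood proxy; if `NULL`, `auto_call` must be supplied.
#' @param grid A [grid_spec()].
#' @param graders List of grader parameter lists (default
#'   [default_graders()]).
#' @param visibility_threshold Ratio threshold in percent.
#' @param auto_call Optional precomputed proxy calls (character vector
#'   aligned with `measurements` rows), bypassing `bscans`.
#' @return Data frame: one row per eye x location with the proxy call, the
#'   three grader calls, the majority call and the adjudication flag.
#' @export
grade_cohort <- function(measurements, bscans = NULL, grid = grid_spec(),
                         graders = default_graders(),
                         visibility_threshold = 60, auto_call = NULL) {
  n <- nrow(measurements)
  if (is.null(auto_call)) {
    stopifnot(!is.null(bscans))
    auto_call <- vapply(seq_len(n), function(i) {
      auto_grade(measurements[i, ], bscans[[measurements$eye_id[i]]], grid,
                 visibility_threshold)
    }, character(1))
  }
  stopifnot(length(auto_call) == n)
  g <- matrix("", n, length(graders))
  maj <- character(n); adj <- logical(n)
  for (i in seq_len(n)) {
    truth <- auto_call[i]
    if (truth == "cannot_determine") {
      g[i, ] <- "cannot_determine"
    } else {
      g[i, ] <- vapply(graders, function(p)
        simulate_grader(truth, p$sensitivity, p$specificity,
                        p$p_undetermined), character(1))
    }
    v <- majority_vote(g[i, ], measurements[i, ], visibility_threshold)
    maj[i] <- v$call; adj[i] <- v$adjudicated
  }
  out <- data.frame(eye_id = measurements$eye_id,
                    location = measurements$location,
                    auto_call = auto_call, stringsAsFactors = FALSE)
  for (k in seq_along(graders)) out[[paste0("grader", k)]] <- g[, k]
  out$majority_call <- maj
  out$adjudicated <- adj
  out
}
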