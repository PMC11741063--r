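# Cohort summary: the Table-2-style report of per-group/location ratio
# means, rank tests, visibility contingency statistics and grader agreement.

GROUPS <- c("young", "middle", "older")

#' Pooled per-group mean from per-location group means
#'
#' The pooled group mean ratio is defined as the arithmetic mean of the six
#' per-location group means (equal location weights, not equal eye weights).
#'
#' @param location_means Numeric vector (one group) or matrix (groups x
#'   locations) of per-location means.
#' @return Numeric vector of pooled means.
#' @export
pooled_from_location_means <- function(location_means) {
  if (is.matrix(location_means)) rowMeans(location_means)
  else mean(location_means)
}

#' Summarize a measured and graded cohort
#'
#' Produces the full cohort report: per-location group means and SDs of the
#' peak-intensity ratio, Kruskal-Wallis across age groups, Spearman of ratio
#' versus age, the 2 x 3 visibility-by-group chi-square with Cramér's V,
#' Fisher's exact tests between distance points within each group, pooled
#' per-group mean ratios and visible fractions, and pairwise grader kappas.
#'
#' @param measurements Measurement table (rows from [measure_eye()], all
#'   eyes x 6 locations, `status == "ok"`).
#' @param gradings Grading table from [grade_cohort()].
#' @param ages Data frame with `eye_id`, `age_years` (and optionally
#'   `age_group`, otherwise derived).
#' @return An object of class `cohort_report`.
#' @export
summarize_cohort <- function(measurements, gradings, ages) {
  stopifnot(all(c("eye_id", "location", "ratio_pct") %in%
                  names(measurements)),
            all(c("eye_id", "location", "majority_call") %in%
                  names(gradings)),
            all(c("eye_id", "age_years") %in% names(ages)))
  if (is.null(ages$age_group))
    ages$age_group <- as.character(age_group_of(ages$age_years))

  want <- expand.grid(eye_id = unique(ages$eye_id), location = LOCATIONS,
                      stringsAsFactors = FALSE)
  have <- measurements[!is.na(measurements$ratio_pct), c("eye_id", "location")]
  key <- function(d) paste(d$eye_id, d$location)
  miss <- setdiff(key(want), key(have))
  if (length(miss))
    stop("missing measurement cells: ", paste(miss, collapse = ", "))

  m <- merge(measurements, ages, by = "eye_id")
  g <- merge(gradings, ages, by = "eye_id")
  m$age_group <- factor(m$age_group, levels = GROUPS)
  g$age_group <- factor(g$age_group, levels = GROUPS)

  means <- sds <- matrix(NA_real_, 3, 6,
                         dimnames = list(GROUPS, LOCATIONS))
  kw <- sp <- data.frame(location = LOCATIONS, stringsAsFactors = FALSE)
  kw$H <- kw$p.value <- sp$r <- sp$p.value <- NA_real_
  kw$degenerate <- FALSE
  vis <- data.frame(location = LOCATIONS, chi2 = NA_real_, df = NA_real_,
                    p.value = NA_real_, cramers_v = NA_real_,
                    degenerate = FALSE, stringsAsFactors = FALSE)
  vis_tables <- list()

  for (li in seq_along(LOCATIONS)) {
    loc <- LOCATIONS[li]
    ml <- m[m$location == loc, ]
    for (gr in GROUPS) {
      x <- ml$ratio_pct[ml$age_group == gr]
      means[gr, loc] <- mean(x)
      sds[gr, loc] <- stats::sd(x)
    }
    groups <- split(ml$ratio_pct, ml$age_group)
    res <- tryCatch(kruskal_wallis(groups), error = function(e) NULL)
    if (is.null(res) || anyNA(unlist(res)) || res$degenerate) {
      kw$degenerate[li] <- TRUE
      if (!is.null(res)) { kw$H[li] <- res$H; kw$p.value[li] <- res$p.value }
    } else {
      kw$H[li] <- res$H; kw$p.value[li] <- res$p.value
    }
    sres <- tryCatch(spearman(ml$age_years, ml$ratio_pct),
                     error = function(e) NULL)
    if (!is.null(sres)) {
      sp$r[li] <- sres$r; sp$p.value[li] <- sres$p.value
    }
    gl <- g[g$location == loc, ]
    tab <- rbind(
      visible = tapply(gl$majority_call == "visible", gl$age_group, sum),
      not_visible = tapply(gl$majority_call == "not_visible",
                           gl$age_group, sum))
    vis_tables[[loc]] <- tab
    cres <- tryCatch(chi_square(tab), error = function(e) NULL)
    if (is.null(cres)) {
      vis$degenerate[li] <- TRUE
    } else {
      vis$chi2[li] <- cres$chi2; vis$df[li] <- cres$df
      vis$p.value[li] <- cres$p.value
      vis$cramers_v[li] <- cramers_v(cres$chi2, sum(tab), 2, 3)
    }
  }

  fisher <- lapply(GROUPS, function(gr) {
    fmat <- matrix(NA_real_, 6, 6, dimnames = list(LOCATIONS, LOCATIONS))
    gg <- g[g$age_group == gr, ]
    for (a in seq_along(LOCATIONS)) for (b in seq_along(LOCATIONS)) {
      if (a >= b) next
      ca <- gg$majority_call[gg$location == LOCATIONS[a]]
      cb <- gg$majority_call[gg$location == LOCATIONS[b]]
      tab <- rbind(c(sum(ca == "visible"), sum(ca == "not_visible")),
                   c(sum(cb == "visible"), sum(cb == "not_visible")))
      fmat[a, b] <- fmat[b, a] <- fisher_exact(tab)
    }
    fmat
  })
  names(fisher) <- GROUPS

  n_eyes <- table(factor(ages$age_group, levels = GROUPS))
  pooled_mean <- pooled_from_location_means(means)
  visible_frac <- vapply(GROUPS, function(gr) {
    gg <- g[g$age_group == gr, ]
    100 * sum(gg$majority_call == "visible") / nrow(gg)
  }, numeric(1))

  grader_cols <- grep("^grader[0-9]+$", names(gradings), value = TRUE)
  kappa <- NULL
  if (length(grader_cols) >= 2) {
    prs <- utils::combn(grader_cols, 2)
    kappa <- matrix(NA_real_, ncol(prs), 6,
                    dimnames = list(apply(prs, 2, paste, collapse = "-"),
                                    LOCATIONS))
    for (pi in seq_len(ncol(prs))) for (loc in LOCATIONS) {
      gl <- gradings[gradings$location == loc, ]
      kappa[pi, loc] <- tryCatch(
        cohens_kappa(gl[[prs[1, pi]]], gl[[prs[2, pi]]]),
        error = function(e) NA_real_)
    }
  }

  rep <- list(group_means = means, group_sds = sds, n_eyes = n_eyes,
              kruskal = kw, spearman = sp, visibility = vis,
              visibility_tables = vis_tables, fisher = fisher,
              pooled_mean_ratio = pooled_mean,
              pooled_visible_pct = visible_frac, kappa = kappa)
  class(rep) <- "cohort_report"
  rep
}

#' @export
print.cohort_report <- function(x, digits = 1, ...) {
  cat("Sub-band/ELM A-scan peak intensity ratios (%), mean ± SD\n")
  for (gr in rownames(x$group_means)) {
    cat(sprintf("  %-6s (n=%2d): ", gr, x$n_eyes[[gr]]))
    cat(paste(sprintf("%s %.0f±%.0f", colnames(x$group_means),
                      x$group_means[gr, ], x$group_sds[gr, ]),
              collapse = "  "), "\n")
  }
  cat("Kruskal-Wallis p: ",
      paste(sprintf("%s %.3f", x$kruskal$location, x$kruskal$p.value),
            collapse = "  "), "\n")
  cat("Spearman r (p) vs age: ",
      paste(sprintf("%s %.3f (%.3f)", x$spearman$location, x$spearman$r,
                    x$spearman$p.value), collapse = "  "), "\n")
  cat("Visibility chi2 (p) / Cramer's V:\n  ",
      paste(sprintf("%s %.2f (%.3f) / %.2f", x$visibility$location,
                    x$visibility$chi2, x$visibility$p.value,
                    x$visibility$cramers_v), collapse = "  "), "\n")
  cat("Pooled mean ratio (%): ",
      paste(sprintf("%s %.1f", names(x$pooled_mean_ratio),
                    x$pooled_mean_ratio), collapse = "  "), "\n")
  cat("Pooled visible (%):    ",
      paste(sprintf("%s %.1f", names(x$pooled_visible_pct),
                    x$pooled_visible_pct), collapse = "  "), "\n")
  invisible(x)
}

#' Flatten a cohort report to a Table-2-style data frame
#'
#' @param report A `cohort_report`.
#' @param round Apply report rounding (means to integers, V to 2 decimals)?
#' @return A data frame with one row per report line and one column per
#'   location.
#' @export
report_to_table <- function(report, round = TRUE) {
  r2 <- function(v, d) if (round) round(v, d) else v
  rows <- list()
  for (gr in GROUPS)
    rows[[paste0("mean_", gr)]] <- r2(report$group_means[gr, ], 0)
  for (gr in GROUPS)
    rows[[paste0("sd_", gr)]] <- r2(report$group_sds[gr, ], 0)
  rows$kruskal_p <- r2(report$kruskal$p.value, 3)
  rows$spearman_r <- r2(report$spearman$r, 3)
  rows$spearman_p <- r2(report$spearman$p.value, 3)
  rows$chi2 <- r2(report$visibility$chi2, 2)
  rows$chi2_p <- r2(report$visibility$p.value, 3)
  rows$cramers_v <- r2(report$visibility$cramers_v, 2)
  out <- as.data.frame(do.call(rbind, rows))
  colnames(out) <- LOCATIONS
  cbind(statistic = names(rows), out, row.names = NULL)
}
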