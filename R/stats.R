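# The cohort statistics battery, implemented from the formulas; base R's
# kruskal.test / cor.test / chisq.test / fisher.test serve as independent
# oracles in the test suite, never as the implementation.

#' Kruskal-Wallis rank test
#'
#' H with tie correction and a chi-square approximation on k - 1 degrees of
#' freedom. Rank-based, hence invariant under strictly monotone transforms.
#'
#' @param samples List of >= 2 nonempty numeric vectors.
#' @return List with `H`, `df`, `p.value`, and `degenerate` (`TRUE` when
#'   all pooled observations are identical, in which case H = 0, p = 1).
#' @export
kruskal_wallis <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (any(vapply(samples, length, 0L) == 0)) stop("empty group")
  x <- unlist(samples, use.names = FALSE)
  g <- rep(seq_along(samples), vapply(samples, length, 0L))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations in total")
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- table(x)
  cval <- 1 - sum(ties^3 - ties) / (n^3 - n)
  df <- length(samples) - 1
  if (cval == 0) {  # all observations identical
    h <- 0
    p <- 1
  } else {
    h <- h / cval
    p <- stats::pchisq(h, df, lower.tail = FALSE)
  }
  list(H = h, df = df, p.value = p, degenerate = cval == 0)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks, with the t approximation on n - 2
#' degrees of freedom for the two-sided p-value (the SPSS convention).
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @return List with `r`, `p.value`, `n`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero variance in ranks: correlation undefined")
  r <- stats::cor(rx, ry)
  n <- length(x)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
  }
  list(r = r, p.value = p, n = n)
}

#' Pearson chi-square test of independence
#'
#' The uncorrected Pearson statistic (no Yates continuity correction), with
#' (r - 1)(c - 1) degrees of freedom.
#'
#' @param counts Nonnegative integer matrix (r x c contingency table).
#' @return List with `chi2`, `df`, `p.value`, `expected`.
#' @export
chi_square <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), nrow(counts) >= 2, ncol(counts) >= 2)
  n <- sum(counts)
  if (n < 1) stop("empty table")
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0))
    stop("zero row or column margin: expected counts are zero")
  e <- outer(rs, cs) / n
  chi2 <- sum((counts - e)^2 / e)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  list(chi2 = chi2, df = df,
       p.value = stats::pchisq(chi2, df, lower.tail = FALSE), expected = e)
}

#' Cramér's V effect size
#'
#' `V = sqrt(chi2 / (n * min(r - 1, c - 1)))`, the strength of association
#' of an r x c contingency table; 0 = no association, values above 0.25
#' already indicate a very strong relationship for tables of this size.
#'
#' @param chi2 Pearson chi-square statistic (>= 0).
#' @param n Total count (>= 1).
#' @param r,c Table dimensions (both >= 2).
#' @return V in \[0, 1\].
#' @export
cramers_v <- function(chi2, n, r, c) {
  stopifnot(chi2 >= 0, n >= 1)
  if (min(r, c) < 2) stop("Cramér's V requires at least a 2 x 2 table")
  sqrt(chi2 / (n * min(r - 1, c - 1)))
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p by hypergeometric enumeration: the sum of probabilities of
#' all tables with the observed margins whose probability does not exceed
#' the observed table's (with a relative tolerance for floating-point
#' ties).
#'
#' @param counts 2 x 2 nonnegative integer matrix.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2)))
    stop("only 2 x 2 tables are supported")
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  m <- sum(counts[1, ]); n2 <- sum(counts[2, ]); k <- sum(counts[, 1])
  if (m == 0 || n2 == 0 || k == 0 || k == m + n2) return(1)
  support <- max(0, k - n2):min(m, k)
  logp <- lchoose(m, support) + lchoose(n2, k - support) -
    lchoose(m + n2, k)
  obs <- logp[support == counts[1, 1]]
  sum(exp(logp[logp <= obs + 1e-7]))
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with expected
#' agreement from the marginal products; ranges from -1 (systematic
#' disagreement) through 0 (chance) to 1 (perfect agreement).
#'
#' @param calls_a,calls_b Equal-length categorical vectors.
#' @return kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(calls_a, calls_b) {
  stopifnot(length(calls_a) == length(calls_b), length(calls_a) >= 1)
  lev <- sort(unique(c(as.character(calls_a), as.character(calls_b))))
  a <- factor(calls_a, levels = lev); b <- factor(calls_b, levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe == 1)
    stop("kappa undefined: both raters constant with identical calls")
  (po - pe) / (1 - pe)
}
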