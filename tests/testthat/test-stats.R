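# Statistics battery, each routine checked against a hand/base-R oracle.

test_that("kruskal_wallis: hand value, ties, invariance, base-R oracle", {
  const <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(const$H, 0)
  expect_equal(const$p.value, 1)
  expect_true(const$degenerate)

  # {1,2},{3,4},{5,6}: rank sums 3,7,11 -> H = 32/7 (hand enumeration)
  s <- list(c(1, 2), c(3, 4), c(5, 6))
  kw <- kruskal_wallis(s)
  expect_equal(kw$H, 32 / 7, tolerance = 1e-12)
  expect_equal(kw$H, oracle_kw_h(s), tolerance = 1e-12)

  # rank-based: invariant under strictly monotone transforms
  set.seed(1)
  x <- list(rnorm(7), rnorm(5) + 1, rnorm(6) - 0.5)
  expect_equal(kruskal_wallis(x)$H,
               kruskal_wallis(lapply(x, function(v) exp(3 * v)))$H,
               tolerance = 1e-12)

  # with ties, against base R
  y <- list(c(1, 2, 2, 3), c(2, 4, 4), c(5, 5, 6, 1))
  ref <- stats::kruskal.test(unlist(y),
                             factor(rep(1:3, lengths(y))))
  mine <- kruskal_wallis(y)
  expect_equal(mine$H, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("spearman: exact ranks, hand case, base-R oracle", {
  expect_equal(spearman(1:8, (1:8)^3)$r, 1)
  expect_equal(spearman(1:8, rev(1:8))$r, -1)
  # x=(1,2,3,4), y=(1,3,2,4): sum d^2 = 2 -> r = 1 - 12/60 = 0.8
  h <- spearman(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(h$r, 0.8, tolerance = 1e-12)
  expect_equal(h$p.value, 0.2, tolerance = 1e-10)  # t approx, n - 2 df

  set.seed(2)
  x <- rnorm(30); y <- x + rnorm(30, sd = 2)
  ref <- stats::cor.test(x, y, method = "spearman")
  expect_equal(spearman(x, y)$r, unname(ref$estimate), tolerance = 1e-10)
  expect_error(spearman(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("chi_square: independence, hand case, symmetry, base-R oracle", {
  # margins-proportional table has chi2 exactly 0
  tab0 <- outer(c(10, 20), c(3, 6, 9)) / 3
  expect_equal(chi_square(tab0)$chi2, 0, tolerance = 1e-12)

  # [[10,5],[5,10]]: all E = 7.5 -> chi2 = 4 * 2.5^2 / 7.5 = 10/3
  t1 <- matrix(c(10, 5, 5, 10), 2, byrow = TRUE)
  r1 <- chi_square(t1)
  expect_equal(r1$chi2, 10 / 3, tolerance = 1e-12)
  expect_equal(r1$df, 1)
  expect_equal(chi_square(t(t1))$chi2, r1$chi2)

  set.seed(3)
  t2 <- matrix(rpois(6, 12) + 1, 2, 3)
  ref <- suppressWarnings(stats::chisq.test(t2, correct = FALSE))
  mine <- chi_square(t2)
  expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("cramers_v reconstructs reported effect sizes", {
  # 2x3 visibility tables with n = 44
  expect_equal(round(cramers_v(6.70, 44, 2, 3), 2), 0.39)
  expect_equal(round(cramers_v(13.10, 44, 2, 3), 2), 0.55)
  expect_equal(cramers_v(0, 100, 3, 4), 0)
  expect_error(cramers_v(5, 44, 1, 3), "2 x 2")
  # internal consistency: V^2 * n * min(r-1, c-1) == chi2
  for (chi2 in c(0.5, 3.74, 12.62)) {
    v <- cramers_v(chi2, 44, 2, 3)
    expect_equal(v^2 * 44 * 1, chi2, tolerance = 1e-9)
  }
})

test_that("fisher_exact: hand case, degenerate margins, symmetry, oracle", {
  perfect <- matrix(c(5, 0, 0, 5), 2, byrow = TRUE)
  expect_equal(fisher_exact(perfect), 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), 1)

  set.seed(4)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 4), 2)
    p <- fisher_exact(tab)
    expect_equal(p, fisher_exact(tab[2:1, 2:1]), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    expect_equal(p, oracle_fisher_p(tab), tolerance = 1e-12)
  }
  expect_error(fisher_exact(matrix(1, 2, 3)), "2 x 2")
})

test_that("cohens_kappa: perfect, hand table, permutation, undefined", {
  a <- rep(c("x", "y"), 10)
  expect_equal(cohens_kappa(a, a), 1)
  # agreement table [[35,15],[15,35]]: p_o = 0.7, p_e = 0.5 -> kappa 0.4
  g1 <- rep(c("v", "v", "n", "n"), c(35, 15, 15, 35))
  g2 <- rep(c("v", "n", "v", "n"), c(35, 15, 15, 35))
  expect_equal(cohens_kappa(g1, g2), 0.4, tolerance = 1e-12)
  # label permutation invariance
  swap <- function(v) ifelse(v == "v", "n", "v")
  expect_equal(cohens_kappa(swap(g1), swap(g2)), 0.4, tolerance = 1e-12)
  expect_error(cohens_kappa(rep("v", 5), rep("v", 5)), "undefined")
})

test_that("summarize_cohort pools and reports per Table-2 conventions", {
  # pooled group mean = mean of the six per-location means
  middle <- c(78, 75, 80, 76, 75, 81)
  older <- c(87, 86, 83, 78, 85, 92)
  expect_equal(round(pooled_from_location_means(middle), 1), 77.5)
  expect_equal(round(pooled_from_location_means(older), 1), 85.2)

  # a minimal 3-eye cohort exercising the full report path
  ages <- data.frame(eye_id = c("a", "b", "c"),
                     age_years = c(30, 50, 70))
  meas <- expand.grid(eye_id = ages$eye_id, location = LOCATIONS,
                      stringsAsFactors = FALSE)
  meas$ratio_pct <- 70
  meas$used_fallback <- FALSE
  grads <- meas[, c("eye_id", "location")]
  grads$auto_call <- grads$majority_call <-
    rep(c("visible", "not_visible"), length.out = nrow(grads))
  grads$grader1 <- grads$grader2 <- grads$grader3 <- grads$majority_call
  grads$adjudicated <- FALSE
  rep1 <- summarize_cohort(meas, grads, ages)
  expect_true(all(rep1$kruskal$degenerate))       # constant ratios
  expect_true(all(rep1$group_sds == 0 | is.na(rep1$group_sds)))
  expect_equal(unname(rep1$pooled_mean_ratio), rep(70, 3))
  expect_true(all(rep1$pooled_visible_pct >= 0 &
                    rep1$pooled_visible_pct <= 100))

  # missing cells are reported by name
  expect_error(summarize_cohort(meas[-1, ], grads, ages),
               "missing measurement cells: a 2N")
})
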