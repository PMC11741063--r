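# Dense-grid rendering oracle, independent of the package's render path:
# evaluates a sum of Gaussian bands on a 0.01-um grid by direct summation
# and characterizes its extrema numerically.

oracle_profile <- function(centers_um, amps, sigmas_um, floor = 0,
                           range_um = c(min(centers_um) - 15,
                                        max(centers_um) + 15),
                           step_um = 0.01) {
  d <- seq(range_um[1], range_um[2], by = step_um)
  v <- rep(floor, length(d))
  for (k in seq_along(centers_um))
    v <- v + amps[k] * exp(-0.5 * ((d - centers_um[k]) / sigmas_um[k])^2)
  list(depth_um = d, intensity = v)
}

oracle_local_maxima <- function(prof) {
  v <- prof$intensity
  i <- 2:(length(v) - 1)
  idx <- i[v[i] > v[i - 1] & v[i] >= v[i + 1]]
  list(depth_um = prof$depth_um[idx], intensity = v[idx], n = length(idx))
}

# Effective sigma of a zero-width band under a Gaussian PSF of given FWHM.
oracle_sigma <- function(intrinsic_um, psf_fwhm_um)
  sqrt(intrinsic_um^2 + (psf_fwhm_um / (2 * sqrt(2 * log(2))))^2)

# Independent two-sided Fisher p for a 2x2 table via the hypergeometric
# distribution (dhyper), distinct from the package's lchoose enumeration.
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  if (m == 0 || n2 == 0 || k == 0 || k == m + n2) return(1)
  support <- max(0, k - n2):min(m, k)
  p <- dhyper(support, m, n2, k)
  sum(p[p <= p[support == tab[1, 1]] * (1 + 1e-7)])
}

# Closed-form (no ties) Kruskal-Wallis H.
oracle_kw_h <- function(samples) {
  x <- unlist(samples)
  g <- rep(seq_along(samples), lengths(samples))
  n <- length(x)
  r <- rank(x)
  12 / (n * (n + 1)) * sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
}
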