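# Independent oracles used across the suite. These deliberately avoid the
# package's analytic code paths: effects come from weighted least squares on
# a full genotype enumeration, folded correlations from Monte Carlo, and
# moments from direct numerical integration.

# HWE x LE weighted least-squares statistical effects by full 3^k
# enumeration per network: the substitution effect is the weighted
# regression of genotypic value on gene content, the dominance deviation
# the coefficient of the orthogonal heterozygosity contrast, and the
# pairwise epistatic effect the coefficient of the product contrast.
wls_effects <- function(arch, p) {
  n <- arch$n_loci
  alpha <- numeric(n)
  dstar <- numeric(n)
  aa_rows <- list()
  for (r in seq_len(nrow(arch$networks))) {
    loci <- arch$networks[r, ]
    k <- length(loci)
    states <- as.matrix(expand.grid(rep(list(0:2), k)))
    pr <- p[loci]
    w <- apply(states, 1L, function(x) prod(stats::dbinom(x, 2, pr)))
    G <- apply(states, 1L, function(x) alphacor:::network_value(arch, x))
    ax <- sweep(states, 2L, 2 * pr)  # centered gene content
    for (c1 in seq_len(k)) {
      pi <- pr[c1]; qi <- 1 - pi
      alpha[loci[c1]] <- sum(w * G * ax[, c1]) / (2 * pi * qi)
      b <- ifelse(states[, c1] == 0, -2 * pi^2,
                  ifelse(states[, c1] == 1, 2 * pi * qi, -2 * qi^2))
      dstar[loci[c1]] <- sum(w * G * b) / (4 * pi^2 * qi^2)
    }
    if (k >= 2L) {
      for (pair in asplit(combn(k, 2L), 2L)) {
        c1 <- pair[1L]; c2 <- pair[2L]
        den <- 4 * pr[c1] * (1 - pr[c1]) * pr[c2] * (1 - pr[c2])
        aa_rows[[length(aa_rows) + 1L]] <- data.frame(
          i = loci[c1], j = loci[c2],
          value = sum(w * G * ax[, c1] * ax[, c2]) / den)
      }
    }
  }
  aa <- if (length(aa_rows)) do.call(rbind, aa_rows)
        else data.frame(i = integer(0), j = integer(0), value = numeric(0))
  list(alpha = alpha, dstar = dstar, alphaalpha = aa)
}

# total genetic variance of an architecture by enumeration (networks are
# independent under LE, so their variances add)
enum_total_variance <- function(arch, p) {
  total <- 0
  for (r in seq_len(nrow(arch$networks))) {
    loci <- arch$networks[r, ]
    k <- length(loci)
    states <- as.matrix(expand.grid(rep(list(0:2), k)))
    pr <- p[loci]
    w <- apply(states, 1L, function(x) prod(stats::dbinom(x, 2, pr)))
    G <- apply(states, 1L, function(x) alphacor:::network_value(arch, x))
    total <- total + sum(w * G^2) - sum(w * G)^2
  }
  total
}

# Monte-Carlo folded-correlation oracle: sample correlation of |X|, |Y| for
# a zero-mean equal-variance bivariate normal with correlation rho
mc_folded_cor <- function(rho, n, seed) {
  set.seed(seed)
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  cor(abs(x), abs(y))
}

# Beta(a,a) heterozygosity moments by direct numerical integration
# (independent of the closed forms in beta_moments)
beta_moments_quadrature <- function(a) {
  h1 <- integrate(function(p) 2 * p * (1 - p) * stats::dbeta(p, a, a),
                  0, 1, rel.tol = 1e-10)$value
  h2 <- integrate(function(p) (2 * p * (1 - p))^2 * stats::dbeta(p, a, a),
                  0, 1, rel.tol = 1e-10)$value
  c(h_bar = h1, h2_bar = h2)
}

# truncated 1/(pq) spectrum moments in closed form (antiderivatives),
# independent of the integrate() route in hill_moments
hill_moments_closed <- function(ne) {
  lo <- 1 / (2 * ne)
  hi <- 1 - lo
  z <- 2 * log((1 - lo) / lo)
  m1 <- 2 * (hi - lo) / z
  anti <- function(p) p^2 / 2 - p^3 / 3  # antiderivative of p(1-p)
  m2 <- 4 * (anti(hi) - anti(lo)) / z
  c(h_bar = m1, h2_bar = m2)
}

random_frequencies <- function(n, lo = 0.05, hi = 0.95) {
  lo + (hi - lo) * runif(n)
}
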