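#' Nonadditive QTL architectures
#'
#' Defines a genotype-to-value map over `n_loci` biallelic loci, built from
#' disjoint networks of `network_size` loci that contribute additively to the
#' total value. Three analytically tractable scenarios are supported, plus an
#' explicit two-locus functional fixture:
#' \describe{
#'   \item{`complete_dominance`}{single-locus networks; the value `scale` is
#'     realized unless the locus is homozygous for the mutant allele (one
#'     copy of the wild allele suffices — the mutant is recessive).}
#'   \item{`complementary`}{multi-locus dominance: the network contributes
#'     `scale` only if *no* member locus is homozygous mutant (a recessive
#'     genotype at any locus knocks the network out).}
#'   \item{`multiplicative`}{pure additive-by-additive action: the network
#'     contributes `scale` times the product of per-locus gene-content terms,
#'     either centered (content - 1, in \{-1, 0, 1\}; default) or raw
#'     (content, in \{0, 1, 2\}). Generates no dominance variance. With raw
#'     coding all substitution effects share one sign, which degenerates the
#'     random-allele correlation; centered coding is the default.}
#'   \item{`functional`}{two-locus networks with explicit functional effects
#'     `a`, `d`, `aa` on locus 1 of each network (additive and dominance
#'     main effects of locus 1 plus the 1x2 additive-by-additive
#'     interaction, in centered coding). Used as a closed-form test fixture
#'     for the classical identity
#'     \eqn{\alpha_1 = a + (q_1 - p_1) d + (p_2 - q_2) aa}.}
#' }
#' Loci beyond the last complete network are not part of any network and
#' carry zero effects.
#'
#' @param scenario one of `"complete_dominance"`, `"complementary"`,
#'   `"multiplicative"`, `"functional"`.
#' @param n_loci total number of loci.
#' @param network_size loci per network; forced to 1 for complete dominance
#'   and 2 for functional; default 5 otherwise.
#' @param scale per-network value scale.
#' @param coding gene-content coding for multiplicative networks.
#' @param functional list with elements `a`, `d`, `aa` for the functional
#'   scenario.
#' @return An object of class `architecture`: list with `scenario`,
#'   `n_loci`, `networks` (matrix, one row per network), `scale`, `coding`,
#'   `functional`.
#' @examples
#' architecture("complementary", n_loci = 10, network_size = 5)
#' @export
architecture <- function(scenario = c("complete_dominance", "complementary",
                                      "multiplicative", "functional"),
                         n_loci, network_size = NULL, scale = 1,
                         coding = c("centered", "raw"), functional = NULL) {
  scenario <- match.arg(scenario)
  coding <- match.arg(coding)
  stopifnot(is.numeric(n_loci), length(n_loci) == 1L, n_loci >= 1)
  n_loci <- as.integer(n_loci)
  k <- switch(scenario,
              complete_dominance = 1L,
              functional = 2L,
              if (is.null(network_size)) 5L else as.integer(network_size))
  if (!is.null(network_size) && as.integer(network_size) != k &&
      scenario %in% c("complete_dominance", "functional"))
    stop("network_size is fixed at ", k, " for scenario ", scenario)
  if (k < 1L) stop("network_size must be >= 1")
  if (n_loci < k) stop("n_loci must be at least network_size")
  n_networks <- n_loci %/% k
  networks <- matrix(seq_len(n_networks * k), nrow = n_networks, ncol = k,
                     byrow = TRUE)
  if (scenario == "functional") {
    if (is.null(functional) ||
        !all(c("a", "d", "aa") %in% names(functional)))
      stop("functional scenario needs functional = list(a=, d=, aa=)")
    functional <- lapply(functional[c("a", "d", "aa")], as.numeric)
  }
  structure(list(scenario = scenario, n_loci = n_loci, networks = networks,
                 network_size = k, scale = scale, coding = coding,
                 functional = functional),
            class = "architecture")
}

#' @export
print.architecture <- function(x, ...) {
  cat(sprintf("QTL architecture: %s, %d loci, %d network(s) of %d, scale %g\n",
              x$scenario, x$n_loci, nrow(x$networks), x$network_size, x$scale))
  if (x$scenario == "multiplicative") cat("  coding:", x$coding, "\n")
  invisible(x)
}

# value of one network given mutant-allele counts at its loci
network_value <- function(arch, counts) {
  s <- arch$scale
  switch(arch$scenario,
         complete_dominance = s * as.numeric(counts[1L] < 2),
         complementary = s * prod(counts < 2),
         multiplicative = {
           cc <- if (arch$coding == "centered") counts - 1 else counts
           s * prod(cc)
         },
         functional = {
           f <- arch$functional
           c1 <- counts[1L] - 1
           c2 <- counts[2L] - 1
           s * (f$a * c1 + f$d * (counts[1L] == 1) + f$aa * c1 * c2)
         })
}

#' Genotypic value of one individual
#'
#' Total genotypic value of a multilocus genotype under an
#' [architecture()]: the sum of the network contributions.
#'
#' @param arch an [architecture()].
#' @param genotypes integer vector of length `n_loci` giving the count of
#'   the mutant allele (0, 1, or 2) at each locus.
#' @return Scalar genotypic value.
#' @export
genotypic_value <- function(arch, genotypes) {
  stopifnot(inherits(arch, "architecture"))
  if (length(genotypes) != arch$n_loci)
    stop("genotypes must have length n_loci = ", arch$n_loci)
  if (any(is.na(genotypes)) || any(!genotypes %in% 0:2))
    stop("genotype counts must be 0, 1 or 2")
  val <- 0
  for (r in seq_len(nrow(arch$networks)))
    val <- val + network_value(arch, genotypes[arch$networks[r, ]])
  val
}

# product over network columns except those in `drop`, row-wise
prod_except <- function(fmat, drop) {
  keep <- setdiff(seq_len(ncol(fmat)), drop)
  if (!length(keep)) return(rep(1, nrow(fmat)))
  out <- fmat[, keep[1L]]
  for (j in keep[-1L]) out <- out * fmat[, j]
  out
}

# per-network factor matrix f(p) whose row product is the network mean
network_factors <- function(arch, p) {
  P <- matrix(p[t(arch$networks)], nrow = nrow(arch$networks),
              ncol = arch$network_size, byrow = TRUE)
  f <- switch(arch$scenario,
              complete_dominance = 1 - P^2,
              complementary = 1 - P^2,
              multiplicative = if (arch$coding == "centered") 2 * P - 1
                               else 2 * P,
              functional = NULL)
  list(P = P, f = f)
}

#' Population mean under HWE and linkage equilibrium
#'
#' Exact expected genotypic value of a population with allele frequencies
#' `p`, assuming Hardy-Weinberg proportions within loci and linkage
#' equilibrium across loci. Two routes are available: the per-scenario
#' closed form (default), and full enumeration of all 3^k genotype
#' combinations per network weighted by their HWE probabilities. The two
#' must agree; enumeration exists as an independent cross-check.
#'
#' @param arch an [architecture()].
#' @param p numeric vector of mutant-allele frequencies, length `n_loci`.
#' @param method `"closed"` or `"enumeration"`.
#' @return Scalar expected value.
#' @export
population_mean <- function(arch, p, method = c("closed", "enumeration")) {
  stopifnot(inherits(arch, "architecture"))
  method <- match.arg(method)
  if (length(p) != arch$n_loci) stop("p must have length n_loci")
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("frequencies must be in [0,1]")
  if (method == "enumeration") return(population_mean_enum(arch, p))
  nf <- network_factors(arch, p)
  if (arch$scenario == "functional") {
    f <- arch$functional
    p1 <- nf$P[, 1L]; p2 <- nf$P[, 2L]
    return(sum(arch$scale * (f$a * (2 * p1 - 1) + f$d * 2 * p1 * (1 - p1) +
                             f$aa * (2 * p1 - 1) * (2 * p2 - 1))))
  }
  sum(arch$scale * apply(nf$f, 1L, prod))
}

population_mean_enum <- function(arch, p) {
  k <- arch$network_size
  states <- as.matrix(expand.grid(rep(list(0:2), k)))
  total <- 0
  for (r in seq_len(nrow(arch$networks))) {
    loci <- arch$networks[r, ]
    pr <- p[loci]
    # HWE genotype probabilities per locus: (q^2, 2pq, p^2) for counts 0,1,2
    w <- apply(states, 1L, function(x)
      prod(ifelse(x == 0, (1 - pr)^2, ifelse(x == 1, 2 * pr * (1 - pr), pr^2))))
    v <- apply(states, 1L, function(x) network_value(arch, x))
    total <- total + sum(w * v)
  }
  total
}

#' Kojima statistical effects of an architecture
#'
#' Statistical (population-dependent) effects defined as scaled derivatives
#' of the population mean \eqn{\mu(p)} with respect to allele frequencies:
#' the substitution effect \eqn{\alpha_i = \frac{1}{2}\partial\mu/\partial
#' p_i}, the dominance deviation \eqn{d^*_i = -\frac{1}{4}\partial^2\mu/
#' \partial p_i^2}, and the pairwise additive-by-additive effect
#' \eqn{(\alpha\alpha)_{ij} = \frac{1}{4}\partial^2\mu/\partial p_i \partial
#' p_j}. All are evaluated analytically from the closed-form mean of the
#' scenario. Cross-locus effects are zero between networks, so
#' `alphaalpha` is stored sparsely as within-network pairs; by convention
#' \eqn{(\alpha\alpha)_{ii} = 0}.
#'
#' @param arch an [architecture()].
#' @param p mutant-allele frequencies, length `n_loci`. Boundary values
#'   (0 or 1) are allowed; derivatives are one-sided there and such loci
#'   are excluded from correlations downstream.
#' @return An object of class `kojima_effects`: list with `alpha`, `dstar`
#'   (numeric vectors, zero for loci outside all networks),
#'   `alphaalpha` (data.frame `i`, `j`, `value` with `i < j`), `p`,
#'   `n_loci`, and `arch`.
#' @examples
#' a <- architecture("complete_dominance", n_loci = 3)
#' kojima_effects(a, p = c(0.1, 0.5, 0.9))$alpha   # equals -p
#' @export
kojima_effects <- function(arch, p) {
  stopifnot(inherits(arch, "architecture"))
  if (length(p) != arch$n_loci) stop("p must have length n_loci")
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("frequencies must be in [0,1]")
  n <- arch$n_loci
  k <- arch$network_size
  s <- arch$scale
  nets <- arch$networks
  covered <- as.vector(t(nets))
  if (length(covered) < n)
    warning(n - length(covered), " loci are outside all networks; ",
            "their effects are zero")
  alpha <- numeric(n)
  dstar <- numeric(n)
  nf <- network_factors(arch, p)
  P <- nf$P

  if (arch$scenario == "complete_dominance") {
    idx <- nets[, 1L]
    alpha[idx] <- -s * P[, 1L]
    dstar[idx] <- s / 2
    aa <- data.frame(i = integer(0), j = integer(0), value = numeric(0))
  } else if (arch$scenario == "functional") {
    f <- arch$functional
    i1 <- nets[, 1L]; i2 <- nets[, 2L]
    p1 <- P[, 1L]; p2 <- P[, 2L]
    alpha[i1] <- s * (f$a + (1 - 2 * p1) * f$d + (2 * p2 - 1) * f$aa)
    alpha[i2] <- s * (2 * p1 - 1) * f$aa
    dstar[i1] <- s * f$d
    dstar[i2] <- 0
    aa <- data.frame(i = pmin(i1, i2), j = pmax(i1, i2),
                     value = rep(s * f$aa, nrow(nets)))
  } else {
    fm <- nf$f
    for (c1 in seq_len(k)) {
      others <- prod_except(fm, c1)
      idx <- nets[, c1]
      if (arch$scenario == "complementary") {
        # mu = s * prod(1 - p^2): d/dp_i = -2 p_i * others
        alpha[idx] <- -s * P[, c1] * others
        dstar[idx] <- s / 2 * others
      } else {
        # multiplicative: factor is linear in p, second own-derivative is 0
        alpha[idx] <- s * others
        dstar[idx] <- 0
      }
    }
    pairs <- if (k >= 2L) combn(k, 2L) else matrix(integer(0), nrow = 2L)
    aa_list <- vector("list", ncol(pairs))
    for (q in seq_len(ncol(pairs))) {
      c1 <- pairs[1L, q]; c2 <- pairs[2L, q]
      rest <- prod_except(fm, c(c1, c2))
      val <- if (arch$scenario == "complementary")
        s * P[, c1] * P[, c2] * rest
      else
        s * rest
      aa_list[[q]] <- data.frame(i = nets[, c1], j = nets[, c2], value = val)
    }
    aa <- if (length(aa_list)) do.call(rbind, aa_list)
          else data.frame(i = integer(0), j = integer(0), value = numeric(0))
  }
  if (nrow(aa)) {
    aa <- aa[order(aa$i, aa$j), ]  # network-major pair order
    rownames(aa) <- NULL
  }
  structure(list(alpha = alpha, dstar = dstar, alphaalpha = aa,
                 p = as.numeric(p), n_loci = n, arch = arch),
            class = "kojima_effects")
}

#' @export
print.kojima_effects <- function(x, ...) {
  cat(sprintf("Kojima statistical effects: %d loci (%s)\n",
              x$n_loci, x$arch$scenario))
  cat(sprintf("  alpha: mean %.4g, sd %.4g; dstar mean %.4g; %d (alpha,alpha) pairs\n",
              mean(x$alpha), sd(x$alpha), mean(x$dstar), nrow(x$alphaalpha)))
  invisible(x)
}

#' Finite-difference cross-check of Kojima effects
#'
#' Recomputes \eqn{\alpha}, \eqn{d^*} and \eqn{(\alpha\alpha)} from the
#' closed-form population mean by Richardson-extrapolated central finite
#' differences (base step `h`). Slow (meant for verification on small
#' architectures); the analytic [kojima_effects()] is the primary route.
#' Frequencies must sit at least `2h` from the boundary. The default step
#' balances truncation against roundoff for the second derivatives: with
#' Richardson extrapolation the truncation error is O(h^4) while roundoff
#' grows as 1/h^2, so h = 1e-3 keeps both near 1e-10.
#'
#' @inheritParams kojima_effects
#' @param h base finite-difference step.
#' @return Same shape as [kojima_effects()].
#' @export
kojima_effects_fd <- function(arch, p, h = 1e-3) {
  stopifnot(inherits(arch, "architecture"))
  if (any(p < 2 * h) || any(p > 1 - 2 * h))
    stop("frequencies too close to the boundary for step h")
  mu <- function(pp) population_mean(arch, pp, method = "closed")
  n <- arch$n_loci
  shift <- function(pp, i, dd) { pp[i] <- pp[i] + dd; pp }
  d1 <- function(i, hh) (mu(shift(p, i, hh)) - mu(shift(p, i, -hh))) / (2 * hh)
  d2 <- function(i, hh)
    (mu(shift(p, i, hh)) - 2 * mu(p) + mu(shift(p, i, -hh))) / hh^2
  dcross <- function(i, j, hh) {
    (mu(shift(shift(p, i, hh), j, hh)) - mu(shift(shift(p, i, hh), j, -hh)) -
     mu(shift(shift(p, i, -hh), j, hh)) + mu(shift(shift(p, i, -hh), j, -hh))) /
      (4 * hh^2)
  }
  rich <- function(fun, ...) (4 * fun(..., hh = h / 2) - fun(..., hh = h)) / 3
  alpha <- vapply(seq_len(n), function(i) 0.5 * rich(d1, i), numeric(1))
  dstar <- vapply(seq_len(n), function(i) -0.25 * rich(d2, i), numeric(1))
  aa0 <- kojima_effects(arch, p)$alphaalpha
  aa <- aa0
  if (nrow(aa))
    aa$value <- vapply(seq_len(nrow(aa)), function(r)
      0.25 * rich(dcross, aa$i[r], aa$j[r]), numeric(1))
  structure(list(alpha = alpha, dstar = dstar, alphaalpha = aa,
                 p = as.numeric(p), n_loci = n, arch = arch),
            class = "kojima_effects")
}

#' Variance components from statistical effects
#'
#' Sums the per-locus contributions
#' \eqn{\sigma^2_A = \sum_i 2p_iq_i \alpha_i^2},
#' \eqn{\sigma^2_D = \sum_i (2p_iq_i)^2 d^{*2}_i}, and
#' \eqn{\sigma^2_{AA} = \sum_{i<j} (2p_iq_i)(2p_jq_j)(\alpha\alpha)^2_{ij}}
#' (within-network pairs only; cross-network effects are zero), plus the
#' mean dominance deviation.
#'
#' @param effects a [kojima_effects()] object.
#' @return A [variance_components] object (with `var_a` possibly zero for
#'   degenerate frequency vectors).
#' @export
effect_variances <- function(effects) {
  stopifnot(inherits(effects, "kojima_effects"))
  p <- effects$p
  het <- 2 * p * (1 - p)
  var_a <- sum(het * effects$alpha^2)
  var_d <- sum(het^2 * effects$dstar^2)
  aa <- effects$alphaalpha
  var_aa <- if (nrow(aa)) sum(het[aa$i] * het[aa$j] * aa$value^2) else 0
  # built directly: a fully fixed population legitimately has var_a = 0
  structure(list(var_a = var_a, var_d = var_d, var_aa = var_aa,
                 mu_d = mean(effects$dstar)),
            class = "variance_components")
}

#' First-order Taylor transfer of substitution effects
#'
#' Predicts substitution effects in a second population from focal-population
#' effects and the per-locus frequency differences \eqn{\epsilon}:
#' \deqn{\hat\alpha_{ib'} = \alpha_{ib} + 2\epsilon_i(-d^*_{ib}) +
#'   2 \sum_j \epsilon_j (\alpha\alpha)_{ijb}.}
#' Exact whenever \eqn{\alpha_i} is linear in every frequency (complete
#' dominance; two-locus multiplicative networks); second-order accurate
#' otherwise.
#'
#' @param effects_b a [kojima_effects()] object for the focal population.
#' @param epsilon per-locus frequency differences `p_bprime - p_b`.
#' @return Numeric vector of predicted substitution effects in b'.
#' @export
taylor_transfer <- function(effects_b, epsilon) {
  stopifnot(inherits(effects_b, "kojima_effects"))
  if (length(epsilon) != effects_b$n_loci)
    stop("epsilon must have length n_loci")
  out <- effects_b$alpha + 2 * epsilon * (-effects_b$dstar)
  aa <- effects_b$alphaalpha
  if (nrow(aa)) {
    idx <- c(aa$i, aa$j)
    val <- c(2 * aa$value * epsilon[aa$j], 2 * aa$value * epsilon[aa$i])
    add <- rowsum(val, idx)
    out[as.integer(rownames(add))] <- out[as.integer(rownames(add))] + add[, 1L]
  }
  out
}

#' True correlation of substitution effects across two populations
#'
#' Pearson correlation across loci of the exact substitution effects in
#' two populations. `mode = "mutant"` correlates the effects as oriented
#' (all alleles taken as the mutant); `mode = "random"` flips the sign of
#' both populations' effects at odd-indexed loci (1-based input order), a
#' deterministic stand-in for randomizing which allele each effect refers
#' to, which restores a zero mean when effects share a sign. Loci fixed
#' (frequency 0 or 1) in either population are excluded; their count is
#' returned as an attribute.
#'
#' @param effects_b,effects_bprime [kojima_effects()] objects on the same
#'   loci (or lists with elements `alpha` and `p`).
#' @param mode `"mutant"` or `"random"`.
#' @return Correlation scalar with attribute `n_excluded`.
#' @export
true_correlation <- function(effects_b, effects_bprime,
                             mode = c("mutant", "random")) {
  mode <- match.arg(mode)
  a_b <- effects_b$alpha
  a_bp <- effects_bprime$alpha
  if (length(a_b) != length(a_bp)) stop("effect vectors differ in length")
  if (mode == "random") {
    odd <- seq_along(a_b) %% 2L == 1L
    a_b[odd] <- -a_b[odd]
    a_bp[odd] <- -a_bp[odd]
  }
  fixed <- effects_b$p %in% c(0, 1) | effects_bprime$p %in% c(0, 1)
  keep <- which(!fixed & is.finite(a_b) & is.finite(a_bp))
  if (length(keep) < 3L) stop("fewer than 3 usable (segregating) loci")
  x <- a_b[keep]; y <- a_bp[keep]
  if (var(x) == 0 || var(y) == 0)
    stop("zero variance of substitution effects; correlation undefined")
  structure(cor(x, y), n_excluded = length(a_b) - length(keep))
}
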