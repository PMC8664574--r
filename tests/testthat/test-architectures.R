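scenarios <- c("complete_dominance", "complementary", "multiplicative")

test_that("genotypic values follow the scenario definitions", {
  comp <- architecture("complementary", n_loci = 5, network_size = 5, scale = 2)
  expect_equal(genotypic_value(comp, rep(1, 5)), 2)   # no recessive homozygote
  expect_equal(genotypic_value(comp, c(2, 1, 1, 1, 1)), 0)  # knocked out

  mult <- architecture("multiplicative", n_loci = 3, network_size = 3)
  expect_equal(genotypic_value(mult, c(1, 0, 2)), 0)  # heterozygote factor 0
  expect_equal(genotypic_value(mult, c(0, 0, 2)), 1)  # (-1)(-1)(+1)
  mult_raw <- architecture("multiplicative", n_loci = 2, network_size = 2,
                           coding = "raw")
  expect_equal(genotypic_value(mult_raw, c(2, 1)), 2)

  dom <- architecture("complete_dominance", n_loci = 3)
  expect_equal(genotypic_value(dom, c(0, 1, 2)), 2)   # two loci escape

  expect_error(genotypic_value(dom, c(0, 1, 3)), "0, 1 or 2")
  expect_error(genotypic_value(dom, c(0, 1)), "length")
})

test_that("closed-form population mean equals full enumeration", {
  p5 <- rep(0.2, 5)
  comp <- architecture("complementary", n_loci = 5, network_size = 5)
  expect_equal(population_mean(comp, p5), 0.96^5)
  expect_equal(population_mean(comp, p5), 0.815373, tolerance = 1e-6)
  expect_equal(population_mean(comp, p5, "enumeration"),
               population_mean(comp, p5), tolerance = 1e-10)

  dom <- architecture("complete_dominance", n_loci = 2)
  expect_equal(population_mean(dom, c(1, 0.3)), 1 - 0.3^2)  # fixed locus: 0

  mult <- architecture("multiplicative", n_loci = 4, network_size = 2)
  expect_equal(population_mean(mult, c(0.5, 0.9, 0.2, 0.8)),
               0 + (2 * 0.2 - 1) * (2 * 0.8 - 1))

  set.seed(51)
  for (sc in scenarios) {
    for (k in if (sc == "complete_dominance") 1 else c(2, 3, 5)) {
      arch <- architecture(sc, n_loci = 2 * k, network_size = k,
                           scale = runif(1, 0.5, 2))
      p <- random_frequencies(2 * k)
      expect_equal(population_mean(arch, p, "closed"),
                   population_mean(arch, p, "enumeration"), tolerance = 1e-10)
    }
  }
  fun <- architecture("functional", n_loci = 4,
                      functional = list(a = 0.4, d = 0.25, aa = 0.6))
  p <- random_frequencies(4)
  expect_equal(population_mean(fun, p, "closed"),
               population_mean(fun, p, "enumeration"), tolerance = 1e-10)
})

test_that("Kojima effects match their closed-form special cases", {
  dom <- architecture("complete_dominance", n_loci = 4)
  p <- c(0.1, 0.35, 0.5, 0.8)
  e <- kojima_effects(dom, p)
  expect_equal(e$alpha, -p)            # recessive deleterious: alpha = -p s
  expect_equal(e$dstar, rep(0.5, 4))
  expect_equal(nrow(e$alphaalpha), 0)

  # linear gene action carries no second-order statistical effects
  addi <- architecture("multiplicative", n_loci = 3, network_size = 1,
                       coding = "raw")
  ea <- kojima_effects(addi, c(0.2, 0.5, 0.9))
  expect_equal(ea$dstar, rep(0, 3))
  expect_equal(nrow(ea$alphaalpha), 0)
  expect_equal(ea$alpha, rep(1, 3))

  comp <- architecture("complementary", n_loci = 5, network_size = 5)
  ec <- kojima_effects(comp, rep(0.2, 5))
  expect_equal(ec$alpha, rep(-0.2 * 0.96^4, 5), tolerance = 1e-9)
  expect_equal(signif(ec$alpha[1], 6), -0.169869)

  # classical two-locus identity alpha1 = a + (q1-p1) d + (p2-q2) aa
  fun <- architecture("functional", n_loci = 2,
                      functional = list(a = 0.3, d = 0.2, aa = 0.4))
  ef <- kojima_effects(fun, c(0.3, 0.7))
  expect_equal(ef$alpha[1], 0.3 + (0.7 - 0.3) * 0.2 + (0.7 - 0.3) * 0.4)
  expect_equal(ef$alpha[2], (0.3 - 0.7) * 0.4)
  expect_equal(ef$dstar, c(0.2, 0))
  expect_equal(ef$alphaalpha$value, 0.4)
})

test_that("uncovered loci get zero effects with a warning", {
  arch <- architecture("complementary", n_loci = 7, network_size = 5)
  expect_warning(e <- kojima_effects(arch, rep(0.3, 7)), "outside")
  expect_equal(e$alpha[6:7], c(0, 0))
  expect_equal(e$dstar[6:7], c(0, 0))
})

test_that("analytic effects agree with the enumeration regression oracle", {
  set.seed(52)
  for (sc in scenarios) {
    for (trial in 1:4) {
      k <- if (sc == "complete_dominance") 1 else sample(c(2, 3, 5), 1)
      arch <- architecture(sc, n_loci = 2 * k, network_size = k,
                           scale = runif(1, 0.5, 2))
      p <- random_frequencies(2 * k)
      e <- kojima_effects(arch, p)
      o <- wls_effects(arch, p)
      expect_equal(e$alpha, o$alpha, tolerance = 1e-8)
      expect_equal(e$dstar, o$dstar, tolerance = 1e-8)
      if (nrow(e$alphaalpha))
        expect_equal(e$alphaalpha$value, o$alphaalpha$value, tolerance = 1e-8)
    }
  }
  fun <- architecture("functional", n_loci = 6,
                      functional = list(a = 0.5, d = -0.3, aa = 0.8))
  p <- random_frequencies(6)
  e <- kojima_effects(fun, p)
  o <- wls_effects(fun, p)
  expect_equal(e$alpha, o$alpha, tolerance = 1e-8)
  expect_equal(e$dstar, o$dstar, tolerance = 1e-8)
  expect_equal(e$alphaalpha$value, o$alphaalpha$value, tolerance = 1e-8)
})

test_that("additive and dominance design scores are orthogonal under HWE", {
  set.seed(53)
  for (trial in 1:10) {
    p <- runif(1, 0.05, 0.95)
    w <- dbinom(0:2, 2, p)
    ax <- 0:2 - 2 * p
    b <- c(-2 * p^2, 2 * p * (1 - p), -2 * (1 - p)^2)
    expect_lt(abs(sum(w * ax * b)), 1e-10)
    expect_lt(abs(sum(w * b)), 1e-10)
  }
})

test_that("analytic derivatives agree with Richardson finite differences", {
  set.seed(54)
  archs <- list(
    architecture("complete_dominance", n_loci = 3),
    architecture("complementary", n_loci = 5, network_size = 5),
    architecture("multiplicative", n_loci = 6, network_size = 3),
    architecture("functional", n_loci = 4,
                 functional = list(a = 0.4, d = 0.2, aa = 0.7)))
  for (arch in archs) {
    p <- random_frequencies(arch$n_loci, 0.1, 0.9)
    e <- kojima_effects(arch, p)
    f <- kojima_effects_fd(arch, p)
    rel <- function(x, y) abs(x - y) / pmax(abs(y), 1)
    expect_lt(max(rel(f$alpha, e$alpha)), 1e-6)
    expect_lt(max(rel(f$dstar, e$dstar)), 1e-6)
    if (nrow(e$alphaalpha))
      expect_lt(max(rel(f$alphaalpha$value, e$alphaalpha$value)), 1e-6)
  }
})

test_that("architectures have their structural variance zeros", {
  set.seed(55)
  for (trial in 1:100) {
    p <- runif(10)
    dom <- architecture("complete_dominance", n_loci = 10)
    vd <- effect_variances(kojima_effects(dom, p))
    expect_identical(vd$var_aa, 0)
    for (coding in c("centered", "raw")) {
      mult <- architecture("multiplicative", n_loci = 10, network_size = 5,
                           coding = coding)
      vm <- effect_variances(kojima_effects(mult, p))
      expect_identical(vm$var_d, 0)
    }
  }
})

test_that("single additive locus at p = 0.5 gives var_a = a^2 / 2", {
  a_eff <- 0.7
  arch <- architecture("multiplicative", n_loci = 1, network_size = 1,
                       coding = "raw", scale = a_eff)
  v <- effect_variances(kojima_effects(arch, 0.5))
  expect_equal(v$var_a, 0.5 * a_eff^2)
  expect_equal(v$var_d, 0)
})

test_that("variance components account for the enumerated total variance", {
  set.seed(56)
  # complete dominance: additive + dominance is the whole genetic variance
  dom <- architecture("complete_dominance", n_loci = 6)
  p <- random_frequencies(6)
  v <- effect_variances(kojima_effects(dom, p))
  expect_equal(v$var_a + v$var_d, enum_total_variance(dom, p),
               tolerance = 1e-10)
  # two-locus multiplicative: additive + additive-by-additive is everything
  mult2 <- architecture("multiplicative", n_loci = 4, network_size = 2)
  p <- random_frequencies(4)
  v2 <- effect_variances(kojima_effects(mult2, p))
  expect_equal(v2$var_a + v2$var_aa, enum_total_variance(mult2, p),
               tolerance = 1e-10)
  # k >= 3: pairwise decomposition omits higher-order epistatic terms
  for (arch in list(architecture("complementary", n_loci = 5, network_size = 5),
                    architecture("multiplicative", n_loci = 5,
                                 network_size = 5))) {
    p <- random_frequencies(5)
    v <- effect_variances(kojima_effects(arch, p))
    expect_lte(v$var_a + v$var_d + v$var_aa,
               enum_total_variance(arch, p) + 1e-10)
  }
})

test_that("Taylor transfer is exact for linear-in-frequency effects", {
  set.seed(57)
  # epsilon = 0 is the identity
  comp <- architecture("complementary", n_loci = 5, network_size = 5)
  p <- random_frequencies(5)
  e <- kojima_effects(comp, p)
  expect_equal(taylor_transfer(e, rep(0, 5)), e$alpha)

  # complete dominance: alpha = -ps is linear, transfer is exact
  dom <- architecture("complete_dominance", n_loci = 6)
  p <- random_frequencies(6)
  eps <- runif(6, -0.04, 0.04)
  pred <- taylor_transfer(kojima_effects(dom, p), eps)
  expect_equal(pred, kojima_effects(dom, p + eps)$alpha, tolerance = 1e-12)

  # two-locus multiplicative: alpha_i linear in the partner frequency
  mult2 <- architecture("multiplicative", n_loci = 4, network_size = 2)
  p <- random_frequencies(4)
  eps <- runif(4, -0.05, 0.05)
  pred2 <- taylor_transfer(kojima_effects(mult2, p), eps)
  expect_equal(pred2, kojima_effects(mult2, p + eps)$alpha, tolerance = 1e-12)
})

test_that("Taylor transfer error scales quadratically for complementary nets", {
  set.seed(58)
  comp <- architecture("complementary", n_loci = 10, network_size = 5)
  p <- random_frequencies(10, 0.2, 0.8)
  eps <- runif(10, -0.05, 0.05)
  err <- function(eps) {
    pred <- taylor_transfer(kojima_effects(comp, p), eps)
    sqrt(sum((pred - kojima_effects(comp, p + eps)$alpha)^2))
  }
  ratio <- err(eps) / err(eps / 2)
  expect_equal(ratio, 4, tolerance = 0.4)
})

test_that("true correlation of effect vectors behaves as a Pearson correlation", {
  comp <- architecture("complementary", n_loci = 10, network_size = 5)
  p <- random_frequencies(10)
  e <- kojima_effects(comp, p)
  expect_equal(as.numeric(true_correlation(e, e, "mutant")), 1)
  expect_equal(as.numeric(true_correlation(e, e, "random")), 1)

  hand_b <- list(alpha = c(-1, -2, -3, -4), p = rep(0.5, 4))
  hand_bp <- list(alpha = c(-1, -2, -3, -5), p = rep(0.5, 4))
  expect_equal(as.numeric(true_correlation(hand_b, hand_bp, "mutant")),
               0.9827, tolerance = 1e-4)

  # fixed loci are excluded and counted
  fb <- list(alpha = c(-1, -2, -3, -4, -9), p = c(0.5, 0.5, 0.5, 0.5, 1))
  fbp <- list(alpha = c(-1, -2, -3, -5, -9), p = c(0.5, 0.5, 0.5, 0.5, 0.7))
  r <- true_correlation(fb, fbp, "mutant")
  expect_equal(attr(r, "n_excluded"), 1L)
  expect_equal(as.numeric(r), 0.9827, tolerance = 1e-4)

  expect_error(true_correlation(list(alpha = c(1, 2), p = c(0.5, 0.5)),
                                list(alpha = c(1, 2), p = c(0.5, 0.5))),
               "fewer than 3")
  con <- list(alpha = rep(1, 4), p = rep(0.5, 4))
  expect_error(true_correlation(con, con, "mutant"), "zero variance")
})

test_that("drifted dominance populations show mutant below random correlation", {
  set.seed(59)
  dom <- architecture("complete_dominance", n_loci = 400)
  p_anc <- sample_ancestral_frequencies(spectrum_beta(0.2), 400)
  pair <- split_and_drift(p_anc, pop_size = 80, t = 30)
  eb <- kojima_effects(dom, pair$p_b)
  ebp <- kojima_effects(dom, pair$p_bprime)
  expect_lt(true_correlation(eb, ebp, "mutant"),
            true_correlation(eb, ebp, "random"))
})
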