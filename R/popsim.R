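#' Sample ancestral allele frequencies from a spectrum
#'
#' Independent draws of mutant-allele frequencies from the declared
#' spectrum. Beta draws that underflow to exactly 0 or 1 are clamped to
#' `[1e-12, 1 - 1e-12]`; the truncated 1/(pq) spectrum cannot produce
#' boundary values by construction (inverse-CDF sampling on the logit
#' scale). A `fixed` spectrum has no distribution and cannot be sampled.
#' Uses the current R random-number stream; call `set.seed()` for
#' reproducibility.
#'
#' @param spec a [spectrum_spec][spectrum_uniform].
#' @param n_loci number of draws.
#' @return Numeric vector of frequencies in (0, 1).
#' @export
sample_ancestral_frequencies <- function(spec, n_loci) {
  if (!inherits(spec, "spectrum_spec")) stop("spec must be a spectrum_spec")
  stopifnot(is.numeric(n_loci), length(n_loci) == 1L, n_loci >= 1)
  n_loci <- as.integer(n_loci)
  switch(spec$kind,
         uniform = runif(n_loci),
         beta = pmin(pmax(rbeta(n_loci, spec$a, spec$a), 1e-12), 1 - 1e-12),
         hill = {
           lo <- 1 / (2 * spec$ne)
           llo <- log(lo / (1 - lo))
           # CDF of 1/(pq) is linear in logit(p); invert on that scale
           u <- runif(n_loci)
           stats::plogis(llo + u * (-2 * llo))
         },
         fixed = stop("cannot sample from a fixed-moments spectrum"),
         stop("unknown spectrum kind: ", spec$kind))
}

#' Wright-Fisher drift of allele frequencies
#'
#' Propagates each locus independently through `t` generations of binomial
#' sampling in a diploid population of size `pop_size`: each generation
#' draws `Binomial(2N, p) / 2N`. Frequencies 0 and 1 are absorbing.
#'
#' @param p starting frequencies.
#' @param pop_size diploid effective size N (>= 2).
#' @param t number of generations (>= 0).
#' @return Drifted frequency vector.
#' @export
drift <- function(p, pop_size, t) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1))
  if (pop_size < 2) stop("pop_size must be >= 2")
  if (t < 0) stop("t must be >= 0")
  n2 <- 2L * as.integer(pop_size)
  for (g in seq_len(t)) p <- rbinom(length(p), n2, p) / n2
  p
}

#' Split an ancestral population and drift two daughters
#'
#' Runs two independent [drift()] trajectories of `t` generations from the
#' same ancestral frequencies, emulating a population split; returns the
#' aligned [frequency_pair]. The expected differentiation between the
#' daughters is the classical \eqn{E[F_{ST}] \approx 1 - (1 - 1/(2N))^t}.
#'
#' @inheritParams drift
#' @param p_anc ancestral frequency vector.
#' @return A [frequency_pair] of the two daughter populations.
#' @export
split_and_drift <- function(p_anc, pop_size, t) {
  frequency_pair(drift(p_anc, pop_size, t), drift(p_anc, pop_size, t))
}

#' Sample observed allele frequencies from a finite sample
#'
#' Observed frequencies from genotyping `n_individuals` diploid individuals
#' drawn under HWE: `Binomial(2n, p) / 2n` per locus.
#'
#' @param p true frequencies.
#' @param n_individuals diploid sample size (>= 1).
#' @return Observed frequency vector.
#' @export
sample_observed_frequencies <- function(p, n_individuals) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1), n_individuals >= 1)
  n2 <- 2L * as.integer(n_individuals)
  rbinom(length(p), n2, p) / n2
}

#' Minor-allele-frequency ascertainment
#'
#' Keeps loci whose minor allele frequency exceeds `maf` in *both*
#' populations simultaneously, mimicking a SNP-chip marker panel.
#'
#' @param pair a [frequency_pair].
#' @param maf threshold in \[0, 0.5).
#' @return List with `pair` (the subset [frequency_pair]) and `kept`
#'   (integer indices of surviving loci).
#' @export
maf_filter <- function(pair, maf) {
  stopifnot(inherits(pair, "frequency_pair"))
  if (is.na(maf) || maf < 0 || maf >= 0.5) stop("maf must lie in [0, 0.5)")
  ok <- pmin(pair$p_b, 1 - pair$p_b) > maf &
        pmin(pair$p_bprime, 1 - pair$p_bprime) > maf
  kept <- which(ok)
  if (!length(kept)) stop("no loci survive ascertainment")
  list(pair = frequency_pair(pair$p_b[kept], pair$p_bprime[kept],
                             pair$locus_ids[kept]),
       kept = kept)
}

fold_na <- function(r) if (is.na(r)) NA_real_ else r2rabs(r)

estimate_record <- function(vc_b, pair_obs, maf, est_moments) {
  m_all <- empirical_moments(pair_obs$p_b)
  d_all <- nei_distance(pair_obs)
  fst_all <- fst_hat(pair_obs)
  r_all <- cor_from_distance(vc_b, d_all, m_all)
  r_snp <- NA_real_; r_snpfst <- NA_real_
  fst_snp <- NA_real_; n_snp <- 0L
  flt <- tryCatch(maf_filter(pair_obs, maf), error = function(e) NULL)
  if (!is.null(flt)) {
    n_snp <- length(flt$kept)
    m_snp <- empirical_moments(flt$pair$p_b)
    r_snp <- cor_from_distance(vc_b, nei_distance(flt$pair), m_snp)
    fst_snp <- fst_hat(flt$pair)
    r_snpfst <- cor_from_fst(vc_b, fst_snp, est_moments)
  }
  list(fst_hat = fst_all, fst_hat_snp = fst_snp, n_snp = n_snp,
       r_hat_all = r_all, r_hat_snp = r_snp, r_hat_snpfst = r_snpfst)
}

#' Divergence experiment: true vs estimated effect correlations
#'
#' The package's verification experiment. For each divergence time `t` on a
#' grid and each replicate: sample ancestral QTL frequencies from
#' `spectrum`; drift two daughter populations of size `pop_size`
#' independently (drift is cumulative along the grid within a replicate);
#' build the nonadditive `scenario` architecture on the loci; compute exact
#' Kojima substitution effects in both populations and from them the *true*
#' correlations (random-allele and mutant-allele orientations); then
#' re-estimate the correlation the way a practitioner would, from observed
#' frequencies of `n_individuals` genotyped individuals per population:
#' \describe{
#'   \item{`r_hat_all`}{Nei-distance form with distance and heterozygosity
#'     moments from all loci.}
#'   \item{`r_hat_snp`}{same, on the MAF-ascertained subset.}
#'   \item{`r_hat_snpfst`}{Fst form with Fst from the ascertained subset and
#'     fixed assumed moments (`estimator_moments`, by default the
#'     U-shape literature constants 0.107/0.018).}
#' }
#' Variance components entering the estimators are the exact ones of the
#' focal population (separating estimand from estimation noise). Mutant
#' variants of each estimator apply the folded-normal transform
#' [r2rabs()].
#'
#' @param scenario architecture scenario (see [architecture()]).
#' @param n_loci number of QTL (default 5000).
#' @param network_size loci per network (1 for complete dominance, else 5).
#' @param spectrum ancestral frequency spectrum. The default Beta(0.04,
#'   0.04) emulates a realistic low-frequency QTL spectrum: about 80% of
#'   loci have minor allele frequency below 0.01 and roughly a tenth
#'   survive SNP-style ascertainment, matching the profile of
#'   coalescent-simulated sequence variants.
#' @param pop_size diploid size of each daughter population (default 300;
#'   with the default grid this spans Fst from 0 to about 0.15).
#' @param t_grid divergence times in generations (default 0 to 100 by 10).
#' @param n_individuals genotyped sample size per population (default 200).
#' @param maf ascertainment threshold (default 0.01).
#' @param replicates replicates per grid point (default 10).
#' @param coding multiplicative gene-content coding.
#' @param scale per-network value scale.
#' @param seed base random seed; replicate r uses `seed + r`.
#' @param estimator_moments spectrum supplying the fixed moments of the
#'   `r_hat_snpfst` estimator.
#' @return An object of class `alphacor_experiment`: list with `records`
#'   (one row per (t, replicate)), `summary` (per-t means and standard
#'   errors), and `config`.
#' @examples
#' ex <- run_experiment("multiplicative", n_loci = 100, t_grid = c(0, 20),
#'                      replicates = 2, pop_size = 100, seed = 1)
#' ex$summary
#' @export
run_experiment <- function(scenario = c("complete_dominance", "complementary",
                                        "multiplicative"),
                           n_loci = 5000,
                           network_size = NULL,
                           spectrum = spectrum_beta(0.04),
                           pop_size = 300,
                           t_grid = seq(0, 100, by = 10),
                           n_individuals = 200,
                           maf = 0.01,
                           replicates = 10,
                           coding = c("centered", "raw"),
                           scale = 1,
                           seed = NULL,
                           estimator_moments = spectrum_hill_literature()) {
  scenario <- match.arg(scenario)
  coding <- match.arg(coding)
  t_grid <- sort(unique(as.integer(t_grid)))
  if (any(t_grid < 0) || !length(t_grid)) stop("t_grid must be nonnegative")
  if (replicates < 1) stop("replicates must be >= 1")
  arch <- architecture(scenario, n_loci = n_loci, network_size = network_size,
                       scale = scale, coding = coding)
  est_m <- if (inherits(estimator_moments, "spectrum_spec"))
    spectrum_moments(estimator_moments) else estimator_moments
  rows <- vector("list", length(t_grid) * replicates)
  ri <- 0L
  for (rep_i in seq_len(replicates)) {
    if (!is.null(seed)) set.seed(seed + rep_i)
    p_anc <- sample_ancestral_frequencies(spectrum, n_loci)
    p_b <- p_anc
    p_bp <- p_anc
    t_done <- 0L
    for (t in t_grid) {
      dt <- t - t_done
      if (dt > 0) {
        p_b <- drift(p_b, pop_size, dt)
        p_bp <- drift(p_bp, pop_size, dt)
        t_done <- t
      }
      eff_b <- kojima_effects(arch, p_b)
      eff_bp <- kojima_effects(arch, p_bp)
      r_rand <- tryCatch(as.numeric(true_correlation(eff_b, eff_bp, "random")),
                         error = function(e) NA_real_)
      r_mut <- tryCatch(as.numeric(true_correlation(eff_b, eff_bp, "mutant")),
                        error = function(e) NA_real_)
      vc_b <- effect_variances(eff_b)
      obs <- frequency_pair(sample_observed_frequencies(p_b, n_individuals),
                            sample_observed_frequencies(p_bp, n_individuals))
      est <- estimate_record(vc_b, obs, maf, est_m)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        t = t, replicate = rep_i,
        fst_hat = est$fst_hat, fst_hat_snp = est$fst_hat_snp,
        n_snp = est$n_snp,
        r_random_true = r_rand, r_mutant_true = r_mut,
        r_hat_all = est$r_hat_all, r_hat_snp = est$r_hat_snp,
        r_hat_snpfst = est$r_hat_snpfst,
        r_hat_all_mutant = fold_na(est$r_hat_all),
        r_hat_snp_mutant = fold_na(est$r_hat_snp),
        r_hat_snpfst_mutant = fold_na(est$r_hat_snpfst))
    }
  }
  records <- do.call(rbind, rows)
  records <- records[order(records$t, records$replicate), ]
  rownames(records) <- NULL
  structure(list(records = records,
                 summary = summarize_experiment(records),
                 config = list(scenario = scenario, n_loci = n_loci,
                               network_size = arch$network_size,
                               spectrum = spectrum, pop_size = pop_size,
                               t_grid = t_grid,
                               n_individuals = n_individuals, maf = maf,
                               replicates = replicates, coding = coding,
                               scale = scale, seed = seed)),
            class = "alphacor_experiment")
}

summarize_experiment <- function(records) {
  cols <- c("fst_hat", "r_random_true", "r_mutant_true",
            "r_hat_all", "r_hat_snp", "r_hat_snpfst")
  out <- lapply(split(records, records$t), function(df) {
    row <- data.frame(t = df$t[1L], n = nrow(df))
    for (cl in cols) {
      v <- df[[cl]]
      row[[paste0(cl, "_mean")]] <- mean(v, na.rm = TRUE)
      row[[paste0(cl, "_se")]] <-
        if (sum(!is.na(v)) > 1L) sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
        else NA_real_
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$t), ]
}

#' @export
print.alphacor_experiment <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Divergence experiment: %s, %d loci, N = %d, %d replicates\n",
              cfg$scenario, cfg$n_loci, cfg$pop_size, cfg$replicates))
  cat("  t grid:", paste(cfg$t_grid, collapse = " "), "\n")
  cat(sprintf("  realized mean Fst range: %.4f .. %.4f\n",
              min(x$summary$fst_hat_mean), max(x$summary$fst_hat_mean)))
  cat(sprintf("  true r_random at max t: %.3f; r_hat_all: %.3f\n",
              x$summary$r_random_true_mean[nrow(x$summary)],
              x$summary$r_hat_all_mean[nrow(x$summary)]))
  invisible(x)
}

#' @export
summary.alphacor_experiment <- function(object, ...) object$summary

#' Plot a divergence experiment
#'
#' True mean correlation of random-allele substitution effects (solid line)
#' against realized Fst, with the three estimators overplotted as points.
#'
#' @param x an `alphacor_experiment`.
#' @param ... passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.alphacor_experiment <- function(x, ...) {
  s <- x$summary
  graphics::plot(s$fst_hat_mean, s$r_random_true_mean, type = "l", lwd = 2,
                 xlab = expression(F[ST]), ylab = "r(alpha_b, alpha_b')",
                 ylim = range(c(s$r_random_true_mean, s$r_hat_all_mean,
                                s$r_hat_snp_mean, s$r_hat_snpfst_mean),
                              na.rm = TRUE),
                 main = x$config$scenario, ...)
  graphics::points(s$fst_hat_mean, s$r_hat_all_mean, pch = 1, col = 2)
  graphics::points(s$fst_hat_mean, s$r_hat_snp_mean, pch = 2, col = 3)
  graphics::points(s$fst_hat_mean, s$r_hat_snpfst_mean, pch = 3, col = 4)
  graphics::legend("bottomleft", bty = "n",
                   legend = c("true", "rHatAll", "rHatSNP", "rHatSNPFst"),
                   lty = c(1, NA, NA, NA), pch = c(NA, 1, 2, 3),
                   col = c(1, 2, 3, 4))
  invisible(x)
}
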