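#' Aligned allele frequencies of two populations
#'
#' Pairs per-locus frequencies of the same reference allele in a focal
#' population `b` and a second population `b'`. The per-locus difference
#' `epsilon = p_bprime - p_b` drives the change in substitution effects.
#'
#' @param p_b,p_bprime numeric vectors of equal length, frequencies in \[0,1\].
#' @param locus_ids optional locus labels (default `L1`, `L2`, ...).
#' @return An object of class `frequency_pair` with elements `locus_ids`,
#'   `p_b`, `p_bprime`, `epsilon`, `n_loci`.
#' @export
frequency_pair <- function(p_b, p_bprime, locus_ids = NULL) {
  if (length(p_b) != length(p_bprime))
    stop("p_b and p_bprime must have equal length")
  if (length(p_b) == 0L) stop("empty frequency pair")
  for (nm in c("p_b", "p_bprime")) {
    p <- get(nm)
    bad <- which(is.na(p) | p < 0 | p > 1)
    if (length(bad))
      stop("frequency outside [0,1] in ", nm, " at locus ", bad[1L])
  }
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_along(p_b))
  if (anyDuplicated(locus_ids)) stop("duplicate locus_ids")
  structure(list(locus_ids = as.character(locus_ids),
                 p_b = as.numeric(p_b), p_bprime = as.numeric(p_bprime),
                 epsilon = as.numeric(p_bprime) - as.numeric(p_b),
                 n_loci = length(p_b)),
            class = "frequency_pair")
}

#' @export
print.frequency_pair <- function(x, ...) {
  cat("Frequency pair:", x$n_loci, "loci\n")
  cat(sprintf("  mean |epsilon| = %.4g, nei_d = %.4g\n",
              mean(abs(x$epsilon)), nei_distance(x)))
  invisible(x)
}

as_frequency_pair <- function(pair, p_bprime = NULL) {
  if (inherits(pair, "frequency_pair")) return(pair)
  frequency_pair(pair, p_bprime)
}

#' Nei minimum genetic distance
#'
#' The mean squared difference of allele frequencies across loci,
#' \eqn{D_{b,b'} = \frac{1}{n}\sum_i (p_{ib'} - p_{ib})^2}. Equals the
#' variance of frequency differences when their mean is zero, and is the
#' numerator of the Fst estimator on the same loci.
#'
#' @param pair a [frequency_pair], or a numeric vector `p_b` (then supply
#'   `p_bprime`).
#' @param p_bprime second frequency vector when `pair` is a plain vector.
#' @return Nonnegative scalar distance.
#' @export
nei_distance <- function(pair, p_bprime = NULL) {
  pair <- as_frequency_pair(pair, p_bprime)
  mean(pair$epsilon^2)
}

#' Fst from allele frequencies of two populations
#'
#' The ratio-of-sums fixation-index estimator
#' \deqn{\hat{F}_{ST} = \frac{\sum_i (p_{ib'} - p_{ib})^2}
#'   {\sum_i [p_{ib'}(1-p_{ib}) + p_{ib}(1-p_{ib'})]}.}
#' Sums are taken over loci before dividing (not a mean of per-locus ratios);
#' loci monomorphic in both populations contribute zero to both sums.
#'
#' @inheritParams nei_distance
#' @return Fst estimate in \[0, 1\].
#' @export
fst_hat <- function(pair, p_bprime = NULL) {
  pair <- as_frequency_pair(pair, p_bprime)
  num <- sum(pair$epsilon^2)
  den <- sum(pair$p_bprime * (1 - pair$p_b) + pair$p_b * (1 - pair$p_bprime))
  if (den <= 0)
    stop("F_ST undefined: all loci fixed identically in both populations")
  num / den
}

#' Convert between Fst and Nei minimum distance
#'
#' Under approximately equal heterozygosities in the two populations,
#' \eqn{D_{b,b'} \approx \frac{F_{ST}}{1 - F_{ST}} \bar{H}_b}.
#' `fst_from_d` is the algebraic inverse, \eqn{F_{ST} = D/(D + \bar{H}_b)}.
#'
#' @param fst fixation index in \[0, 1).
#' @param d Nei minimum distance (nonnegative).
#' @param h_bar mean heterozygosity of the focal population, in (0, 0.5\].
#' @return The converted distance (`d_from_fst`) or index (`fst_from_d`).
#' @export
d_from_fst <- function(fst, h_bar) {
  stopifnot(is.numeric(fst), length(fst) == 1L,
            is.numeric(h_bar), length(h_bar) == 1L)
  if (is.na(fst) || fst < 0 || fst >= 1)
    stop("fst must lie in [0, 1); fst = 1 is degenerate")
  if (is.na(h_bar) || h_bar <= 0 || h_bar > 0.5)
    stop("h_bar must lie in (0, 0.5]")
  fst / (1 - fst) * h_bar
}

#' @rdname d_from_fst
#' @export
fst_from_d <- function(d, h_bar) {
  stopifnot(is.numeric(d), length(d) == 1L, d >= 0,
            is.numeric(h_bar), length(h_bar) == 1L, h_bar > 0)
  d / (d + h_bar)
}

#' Fst between two generations of one population
#'
#' For two time points separated by `delta_t` generations in a population
#' with a steady inbreeding rate `delta_f` per generation, the drift
#' differentiation is approximately \eqn{F_{ST} \approx \Delta t \,
#' \Delta F / 2} (half the increase in average relationship).
#'
#' @param delta_t nonnegative number of generations between the two cohorts.
#' @param delta_f inbreeding rate per generation, in \[0, 1). Typical
#'   livestock values are at most 0.01.
#' @return Fst approximation; errors if it reaches 1 (horizon too long for
#'   the linear approximation).
#' @export
fst_from_generations <- function(delta_t, delta_f) {
  stopifnot(is.numeric(delta_t), length(delta_t) == 1L,
            is.numeric(delta_f), length(delta_f) == 1L)
  if (is.na(delta_t) || delta_t < 0) stop("delta_t must be >= 0")
  if (is.na(delta_f) || delta_f < 0 || delta_f >= 1)
    stop("delta_f must lie in [0, 1)")
  fst <- delta_t * delta_f / 2
  if (fst >= 1) stop("approximation invalid for this horizon (t*dF/2 >= 1)")
  fst
}
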