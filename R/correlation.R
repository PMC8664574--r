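#' Variance components of the focal population
#'
#' Additive (\eqn{\sigma^2_A}), dominance (\eqn{\sigma^2_D}) and
#' additive-by-additive (\eqn{\sigma^2_{AA}}) variances, in any consistent
#' unit (e.g. ratios of phenotypic variance). `mu_d`, the mean dominance
#' deviation (basis of inbreeding depression), is carried for documentation:
#' the factorization used by the correlation forecast folds
#' \eqn{Var(d^*) + E^2(d^*)} into \eqn{\sigma^2_D}, so the supplied
#' `var_d` must already be that aggregate.
#'
#' @param var_a additive variance, strictly positive.
#' @param var_d dominance variance, nonnegative.
#' @param var_aa additive-by-additive variance, nonnegative.
#' @param mu_d mean dominance deviation (default 0; informational).
#' @return An object of class `variance_components`.
#' @export
variance_components <- function(var_a, var_d = 0, var_aa = 0, mu_d = 0) {
  stopifnot(is.numeric(var_a), is.numeric(var_d), is.numeric(var_aa))
  if (is.na(var_a) || var_a <= 0) stop("var_a must be > 0")
  if (is.na(var_d) || var_d < 0) stop("var_d must be >= 0")
  if (is.na(var_aa) || var_aa < 0) stop("var_aa must be >= 0")
  structure(list(var_a = var_a, var_d = var_d, var_aa = var_aa, mu_d = mu_d),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("Variance components: var_a = %g, var_d = %g, var_aa = %g",
              x$var_a, x$var_d, x$var_aa))
  if (!identical(x$mu_d, 0)) cat(sprintf(", mu_d = %g", x$mu_d))
  cat("\n")
  invisible(x)
}

as_variance_components <- function(vc) {
  if (inherits(vc, "variance_components")) return(vc)
  if (is.numeric(vc) && length(vc) >= 3L)
    return(variance_components(vc[[1L]], vc[[2L]], vc[[3L]]))
  stop("expected a variance_components object or a numeric triple")
}

#' Forecast ratio of substitution-effect variances across populations
#'
#' The variance of substitution effects seen from the focal population b,
#' relative to the (larger) variance forecast for a population at Nei
#' distance `d`:
#' \deqn{\frac{Var(\alpha_b)}{Var(\alpha_{b'})} =
#'   \frac{\sigma^2_A}{\sigma^2_A + D_{b,b'}\left[4 \frac{\bar{H}}{\bar{H^2}}
#'   \sigma^2_D + \frac{8}{\bar{H}} \sigma^2_{AA}\right]}.}
#' The number of loci cancels and is not required. This ratio is also the
#' squared correlation of substitution effects between the two populations.
#'
#' @param vc a [variance_components] object (or numeric triple).
#' @param d Nei minimum distance between the populations, nonnegative.
#' @param m a [het_moments] object for the focal population (or assumed
#'   spectrum); `h_bar` and `h2_bar` must be positive.
#' @return Scalar ratio in (0, 1\].
#' @export
forecast_variance_ratio <- function(vc, d, m) {
  vc <- as_variance_components(vc)
  stopifnot(is.numeric(d), length(d) == 1L)
  if (is.na(d) || d < 0) stop("distance d must be >= 0")
  if (!inherits(m, "het_moments")) stop("m must be a het_moments object")
  if (m$h_bar <= 0) stop("h_bar must be positive")
  if (m$h2_bar <= 0) stop("h2_bar must be positive")
  nonadd <- 4 * (m$h_bar / m$h2_bar) * vc$var_d + (8 / m$h_bar) * vc$var_aa
  vc$var_a / (vc$var_a + d * nonadd)
}

#' Correlation of substitution effects from Nei distance
#'
#' The forecast correlation of random-allele substitution effects between
#' the focal population and a population at Nei minimum distance `d`:
#' the square root of [forecast_variance_ratio()], since
#' \eqn{r = Var(\alpha_b)/\sqrt{Var(\alpha_b) Var(\alpha_{b'})}}.
#' Equals 1 iff `d = 0` or both nonadditive variances vanish.
#'
#' @inheritParams forecast_variance_ratio
#' @return Correlation in (0, 1\].
#' @export
cor_from_distance <- function(vc, d, m) {
  sqrt(forecast_variance_ratio(vc, d, m))
}

#' Correlation of substitution effects from Fst
#'
#' The Fst form of the forecast, using
#' \eqn{D_{b,b'} \approx \frac{F_{ST}}{1-F_{ST}} \bar{H}_b}:
#' \deqn{r(\alpha_b, \alpha_{b'}) \approx \sqrt{\frac{\sigma^2_A}
#'   {\sigma^2_A + \frac{F_{ST}}{1-F_{ST}}\left(4 \frac{\bar{H}^2}{\bar{H^2}}
#'   \sigma^2_D + 8 \sigma^2_{AA}\right)}}.}
#' Identical to `cor_from_distance(vc, d_from_fst(fst, m$h_bar), m)`.
#'
#' @inheritParams forecast_variance_ratio
#' @param fst fixation index in \[0, 1).
#' @return Correlation in (0, 1\].
#' @export
cor_from_fst <- function(vc, fst, m) {
  if (!inherits(m, "het_moments")) stop("m must be a het_moments object")
  cor_from_distance(vc, d_from_fst(fst, m$h_bar), m)
}

#' Correlation of substitution effects under pure additive-by-additive action
#'
#' When dominance variance is negligible the heterozygosity moments cancel
#' and the forecast reduces to
#' \eqn{r \approx \sqrt{\sigma^2_A / (\sigma^2_A + 8 \frac{F_{ST}}{1-F_{ST}}
#' \sigma^2_{AA})}}. With `linearized = TRUE` the small-x approximation
#' \eqn{1/(1+x) \approx 1-x} is applied on the squared scale before the
#' square root (clipped below at zero); it is clearly an approximation and
#' overstates the decay for large `x`.
#'
#' @param var_a additive variance, > 0.
#' @param var_aa additive-by-additive variance, >= 0.
#' @param fst fixation index in \[0, 1).
#' @param linearized use the linearized form (default `FALSE`, exact form).
#' @return Correlation in \[0, 1\].
#' @export
cor_epistasis_only <- function(var_a, var_aa, fst, linearized = FALSE) {
  if (is.na(var_a) || var_a <= 0) stop("var_a must be > 0")
  if (is.na(var_aa) || var_aa < 0) stop("var_aa must be >= 0")
  if (is.na(fst) || fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  x <- 8 * fst / (1 - fst) * var_aa / var_a
  if (linearized) sqrt(max(0, 1 - x)) else sqrt(1 / (1 + x))
}

#' Correlation of substitution effects across generations
#'
#' Forecast for two cohorts of one population `delta_t` generations apart
#' with inbreeding rate `delta_f` per generation, via
#' \eqn{F_{ST} \approx \Delta t \, \Delta F / 2} and the Fst form of the
#' correlation.
#'
#' @inheritParams forecast_variance_ratio
#' @inheritParams fst_from_generations
#' @return Correlation in (0, 1\].
#' @export
cor_generations <- function(vc, delta_t, delta_f, m) {
  cor_from_fst(vc, fst_from_generations(delta_t, delta_f), m)
}

#' Folded-normal transform: random-allele to mutant-allele correlation
#'
#' Converts the correlation \eqn{\rho} of substitution effects of randomly
#' oriented alleles (zero-mean) into the correlation of absolute effects
#' (mutant-allele orientation), assuming a zero-mean equal-variance
#' bivariate normal: \eqn{|\alpha|} follows a folded normal, and
#' \deqn{r_{|{\cdot}|} = \frac{\frac{2}{\pi}\left(\sqrt{1-\rho^2} +
#'   \rho \arcsin \rho\right) - \frac{2}{\pi}}{1 - \frac{2}{\pi}}.}
#' Continuous and monotone increasing on \[0, 1\], with
#' \eqn{r_{|\cdot|} \le \rho} on (0, 1). The folded correlation is an even
#' function of \eqn{\rho}; for negative input the signed analogue
#' `-r2rabs(|rho|)` is returned.
#'
#' @param rho correlation in \[-1, 1\] (vectorized).
#' @return Folded (absolute-value) correlation, same length as `rho`.
#' @examples
#' r2rabs(0.85)  # about 0.68
#' @export
r2rabs <- function(rho) {
  if (any(is.na(rho)) || any(abs(rho) > 1))
    stop("rho must lie in [-1, 1]")
  s <- sign(rho)
  r <- abs(rho)
  k <- 2 / pi
  s * (k * (sqrt(1 - r^2) + r * asin(r)) - k) / (1 - k)
}

#' Forecast the correlation of QTL substitution effects
#'
#' The package's central estimator. Given the focal population's variance
#' components and heterozygosity moments, and exactly one measure of the
#' separation between the two populations — a Nei minimum distance `d`, a
#' fixation index `fst`, or a generational horizon (`delta_t`, `delta_f`) —
#' it forecasts the correlation of substitution effects of a randomly
#' oriented allele, and (via the folded-normal transform) of the
#' mutant-oriented (absolute) effects.
#'
#' @param vc a [variance_components] object, or numeric triple
#'   `(var_a, var_d, var_aa)`.
#' @param d Nei minimum distance between populations.
#' @param fst fixation index between populations.
#' @param delta_t generations between the two cohorts.
#' @param delta_f inbreeding rate per generation (required with `delta_t`).
#' @param moments a [het_moments] object, or a
#'   [spectrum_spec][spectrum_uniform] to take moments from.
#' @return An object of class `substitution_correlation`: list with
#'   `r_random`, `r_mutant`, `method` (`"nei_d"`, `"fst"` or
#'   `"generations"`), `variance_ratio`, and the inputs.
#' @examples
#' pig <- variance_components(var_a = 0.092, var_d = 0.020, var_aa = 0.016)
#' substitution_correlation(pig, fst = 0.16,
#'                          moments = spectrum_hill_literature())
#' @export
substitution_correlation <- function(vc, d = NULL, fst = NULL,
                                     delta_t = NULL, delta_f = NULL,
                                     moments) {
  vc <- as_variance_components(vc)
  if (inherits(moments, "spectrum_spec")) moments <- spectrum_moments(moments)
  if (!inherits(moments, "het_moments"))
    stop("moments must be a het_moments or spectrum_spec object")
  given <- c(d = !is.null(d), fst = !is.null(fst), gen = !is.null(delta_t))
  if (sum(given) != 1L)
    stop("supply exactly one of: d, fst, or (delta_t, delta_f)")
  if (given[["gen"]]) {
    if (is.null(delta_f)) stop("delta_f is required with delta_t")
    fst <- fst_from_generations(delta_t, delta_f)
    method <- "generations"
    d_used <- d_from_fst(fst, moments$h_bar)
  } else if (given[["fst"]]) {
    method <- "fst"
    d_used <- d_from_fst(fst, moments$h_bar)
  } else {
    method <- "nei_d"
    d_used <- d
  }
  ratio <- forecast_variance_ratio(vc, d_used, moments)
  r <- sqrt(ratio)
  structure(list(r_random = r, r_mutant = r2rabs(r), method = method,
                 variance_ratio = ratio, d = d_used, fst = fst,
                 delta_t = delta_t, delta_f = delta_f,
                 vc = vc, moments = moments),
            class = "substitution_correlation")
}

#' @export
print.substitution_correlation <- function(x, digits = 4, ...) {
  cat("Forecast correlation of QTL substitution effects\n")
  lab <- switch(x$method,
                nei_d = sprintf("Nei distance D = %.4g", x$d),
                fst = sprintf("Fst = %.4g (D = %.4g)", x$fst, x$d),
                generations = sprintf("%g generations at dF = %g (Fst = %.4g)",
                                      x$delta_t, x$delta_f, x$fst))
  cat("  separation :", lab, "\n")
  cat(sprintf("  components : var_a = %g, var_d = %g, var_aa = %g\n",
              x$vc$var_a, x$vc$var_d, x$vc$var_aa))
  cat(sprintf("  moments    : h_bar = %.4g, h2_bar = %.4g\n",
              x$moments$h_bar, x$moments$h2_bar))
  cat(sprintf("  r_random   : %.*f\n", digits, x$r_random))
  cat(sprintf("  r_mutant   : %.*f   (folded-normal transform)\n",
              digits, x$r_mutant))
  invisible(x)
}

#' @export
summary.substitution_correlation <- function(object, ...) {
  out <- data.frame(method = object$method,
                    d = object$d,
                    fst = if (is.null(object$fst)) NA_real_ else object$fst,
                    variance_ratio = object$variance_ratio,
                    r_random = object$r_random,
                    r_mutant = object$r_mutant,
                    stringsAsFactors = FALSE)
  class(out) <- c("summary.substitution_correlation", "data.frame")
  out
}
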