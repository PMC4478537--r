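# Regularized incomplete-gamma shorthands. Q(a, x) is the upper tail
# Gamma(a, x)/Gamma(a); P(a, x) the lower. All closed forms below are
# kept in regularized form for stability at large shape.
reg_gamma_upper <- function(a, x) pgamma(x, shape = a, lower.tail = FALSE)
reg_gamma_lower <- function(a, x) pgamma(x, shape = a, lower.tail = TRUE)

new_stationary_variance <- function(total, from_large, from_small,
                                    n_large_expected, n_loci) {
  structure(list(total = total, from_large = from_large,
                 from_small = from_small,
                 n_large_expected = n_large_expected,
                 frac_small = 1 - n_large_expected / n_loci,
                 n_loci = n_loci),
            class = "stationary_variance")
}

#' @export
print.stationary_variance <- function(x, ...) {
  cat(sprintf("Stationary genetic variance (l = %d loci)\n", x$n_loci))
  cat(sprintf("  total       %.6g\n  from large  %.6g\n  from small  %.6g\n",
              x$total, x$from_large, x$from_small))
  cat(sprintf("  expected large-effect loci %.4g (f_s = %.4g)\n",
              x$n_large_expected, x$frac_small))
  invisible(x)
}

#' Stationary genetic variance by quadrature over an effect density
#'
#' In the stationary state each large-effect locus (\eqn{\gamma >
#' \hat\gamma}) contributes \eqn{\hat\gamma^2/2} to the genetic variance
#' and each small-effect locus \eqn{\gamma^2/2}, so for an effect
#' density \eqn{p(\gamma)} on \eqn{(0, \infty)}
#' \deqn{c_2^* = \frac{\ell}{2}\left[\hat\gamma^2
#'   \int_{\hat\gamma}^\infty p(\gamma)\,d\gamma +
#'   \int_0^{\hat\gamma} \gamma^2 p(\gamma)\,d\gamma\right].}
#' This generic quadrature route is the independent check on the
#' gamma-family closed form [stationary_variance_gamma()].
#'
#' @param density function of one argument: the effect density, which
#'   must integrate to 1 over `support` within `1e-6`.
#' @param n_loci positive integer, number of loci \eqn{\ell}.
#' @param threshold nonnegative effect threshold \eqn{\hat\gamma}.
#' @param support numeric length-2 vector bounding the density's
#'   support; narrow this for sharply concentrated densities that
#'   adaptive quadrature would otherwise miss on \eqn{(0,\infty)}.
#' @return A `"stationary_variance"` object with fields `total`,
#'   `from_large`, `from_small`, `n_large_expected`, `frac_small`.
#' @export
stationary_variance_quadrature <- function(density, n_loci, threshold,
                                           support = c(0, Inf)) {
  stopifnot(is.function(density), n_loci >= 1, threshold >= 0,
            length(support) == 2, support[1] >= 0,
            support[1] < support[2])
  quad <- function(f, lo, hi) {
    if (lo >= hi) return(0)
    integrate(f, lo, hi, abs.tol = 1e-10, rel.tol = 1e-10)$value
  }
  norm <- quad(density, support[1], support[2])
  if (abs(norm - 1) > 1e-6)
    stop(sprintf("effect density integrates to %.8g, not 1", norm))
  tail_mass <- quad(density, max(threshold, support[1]), support[2])
  small_m2 <- quad(function(g) g^2 * density(g), support[1],
                   min(threshold, support[2]))
  new_stationary_variance(
    total = n_loci / 2 * (threshold^2 * tail_mass + small_m2),
    from_large = n_loci / 2 * threshold^2 * tail_mass,
    from_small = n_loci / 2 * small_m2,
    n_large_expected = n_loci * tail_mass,
    n_loci = n_loci)
}

#' Stationary genetic variance for gamma-distributed effects
#'
#' Closed form of the stationary variance for the gamma effect
#' distribution with shape `k` and mean \eqn{\bar\gamma}, in terms of
#' upper incomplete gamma functions \eqn{\Gamma(a, b)}:
#' \deqn{c_2^* = \frac{\ell\hat\gamma^2}{2}\left[
#'   \frac{\Gamma(k, k\gamma_r)}{\Gamma(k)} +
#'   \frac{\Gamma(2+k) - \Gamma(2+k, k\gamma_r)}{\gamma_r^2 k^2 \Gamma(k)}
#'   \right], \qquad \gamma_r = \hat\gamma/\bar\gamma.}
#' The first bracketed term is the large-effect contribution, the second
#' the small-effect contribution. For `k = 1` it reduces to
#' \eqn{\ell\bar\gamma^2(1 - e^{-\gamma_r}(1 + \gamma_r))}. Limits: the
#' House-of-Cards variance \eqn{\ell\hat\gamma^2/2 = 4\mu\ell/s} as
#' \eqn{\gamma_r \to 0} (all effects large) and
#' \eqn{\ell\bar\gamma^2(k+1)/(2k)} as \eqn{\gamma_r \to \infty}.
#'
#' @param config an [effect_config()].
#' @param n_loci positive integer \eqn{\ell}.
#' @return A `"stationary_variance"` object (see
#'   [stationary_variance_quadrature()]).
#' @examples
#' cfg <- effect_config(shape = 1, mean_effect = 0.1, threshold = 0.063)
#' stationary_variance_gamma(cfg, n_loci = 1000)$total  # 1.32
#' @export
stationary_variance_gamma <- function(config, n_loci) {
  stopifnot(inherits(config, "effect_config"), n_loci >= 1)
  k <- config$shape
  gr <- config$ratio
  ghat <- config$threshold
  if (gr == 0) {          # threshold 0: every effect is large
    return(new_stationary_variance(0, 0, 0, n_loci, n_loci))
  }
  tail_mass <- reg_gamma_upper(k, k * gr)
  # Gamma(2+k) - Gamma(2+k, x) = Gamma(2+k) P(2+k, x) and
  # Gamma(2+k)/Gamma(k) = k (k+1), so the small-effect bracket is
  # (k+1)/k * P(2+k, k*gr) / gr^2.
  small_term <- (k + 1) / k * reg_gamma_lower(2 + k, k * gr) / gr^2
  scale <- n_loci * ghat^2 / 2
  new_stationary_variance(
    total = scale * (tail_mass + small_term),
    from_large = scale * tail_mass,
    from_small = scale * small_term,
    n_large_expected = n_loci * tail_mass,
    n_loci = n_loci)
}

#' Expected fraction of small effects under the gamma distribution
#'
#' The probability mass of the gamma effect distribution below the
#' threshold \eqn{\hat\gamma}:
#' \deqn{f_s = 1 - \frac{\Gamma(k, k\gamma_r)}{\Gamma(k)} =
#'   P(k, k\gamma_r),}
#' the regularized lower incomplete gamma. For exponential effects
#' (`k = 1`) this is \eqn{1 - e^{-\gamma_r}}; for small
#' \eqn{k\gamma_r}, \eqn{f_s \approx (k\gamma_r)^k / k!}.
#'
#' @param config an [effect_config()], or a positive shape `k` if
#'   `ratio` is also given.
#' @param ratio optional \eqn{\gamma_r = \hat\gamma/\bar\gamma} when
#'   `config` is a bare shape.
#' @return `f_s` in `[0, 1]`.
#' @export
frac_small_gamma <- function(config, ratio = NULL) {
  if (inherits(config, "effect_config")) {
    k <- config$shape; gr <- config$ratio
  } else {
    k <- config; gr <- ratio
    stopifnot(is.numeric(k), k > 0, is.numeric(gr), gr >= 0)
  }
  reg_gamma_lower(k, k * gr)
}

# Invert f_s = P(k, k*gr) for gr. Monotone in gr; solved on the log
# scale because small shapes push the root to very small ratios
# (P(k, x) ~ x^k near zero).
ratio_for_frac_small <- function(shape, frac_small) {
  stopifnot(shape > 0, frac_small > 0, frac_small < 1)
  f <- function(lg) reg_gamma_lower(shape, shape * exp(lg)) - frac_small
  lo <- log(1e-30); hi <- log(1e6)
  if (f(lo) > 0 || f(hi) < 0)
    stop(sprintf("f_s = %g not bracketed for shape %g: f(lo)=%.3g f(hi)=%.3g",
                 frac_small, shape, f(lo), f(hi)))
  exp(uniroot(f, c(lo, hi), tol = 1e-13)$root)
}

#' Small-effect share of the stationary variance, exponential effects
#'
#' For exponentially distributed effects the ratio
#' \eqn{c^*_{2,\mathrm{small}}/c_2^*} is a function of the fraction of
#' small effects alone:
#' \deqn{\frac{c^*_{2,\mathrm{small}}}{c_2^*} =
#'  \frac{2 f_s + (1-f_s)\ln(1-f_s)\,(2 - \ln(1-f_s))}
#'       {2 f_s + 2 (1-f_s)\ln(1-f_s)}.}
#' It grows as \eqn{f_s/3} for small \eqn{f_s} and approaches 1 as
#' \eqn{f_s \to 1}: even a majority of small-effect loci contributes a
#' minority of the variance.
#'
#' @param frac_small `f_s` in `[0, 1]` (the boundary values return the
#'   limits 0 and 1).
#' @return Share in `[0, 1]`.
#' @examples
#' small_share_exponential(0.5)  # ~0.217, prints as 21%
#' @export
small_share_exponential <- function(frac_small) {
  stopifnot(frac_small >= 0, frac_small <= 1)
  if (frac_small == 0) return(0)
  if (frac_small == 1) return(1)
  l1 <- log1p(-frac_small)
  (2 * frac_small + (1 - frac_small) * l1 * (2 - l1)) /
    (2 * frac_small + 2 * (1 - frac_small) * l1)
}

#' Small-effect share of the stationary variance, general gamma shape
#'
#' For a general shape `k` the share has no closed form in `f_s`:
#' the ratio \eqn{\gamma_r} is recovered from `f_s` by a monotone root
#' find on the fraction-small relation, and the small-effect term of the
#' closed-form stationary variance is then evaluated relative to the
#' total. At `k = 1` this agrees with [small_share_exponential()].
#'
#' @param shape positive gamma shape `k`.
#' @param frac_small `f_s` in `(0, 1)`.
#' @return Share in `[0, 1]`.
#' @examples
#' small_share_gamma(2, 0.1)  # ~0.049, prints as 5%
#' @export
small_share_gamma <- function(shape, frac_small) {
  stopifnot(shape > 0, frac_small > 0, frac_small < 1)
  gr <- ratio_for_frac_small(shape, frac_small)
  # n_loci and gamma_hat cancel in the ratio; unit values suffice
  sv <- stationary_variance_gamma(
    effect_config(shape = shape, mean_effect = 1 / gr, threshold = 1), 1)
  sv$from_small / sv$total
}

#' Fraction of small effects giving equal variance contributions
#'
#' Solves `small_share_gamma(shape, f_s) = 1/2` for `f_s`: the fraction
#' of small-effect loci needed before small and large effects contribute
#' equally to the stationary variance. Because individual small effects
#' contribute little, this fraction is large (0.89, 0.83, 0.77 for
#' shapes 1/2, 1, 2) and decreases as the distribution narrows.
#'
#' @param shape positive gamma shape `k`.
#' @param tol absolute tolerance of the root find.
#' @return `f_s` in `(0, 1)`.
#' @export
fs_for_equal_share <- function(shape, tol = 1e-6) {
  stopifnot(shape > 0)
  uniroot(function(f) small_share_gamma(shape, f) - 0.5,
          c(1e-3, 1 - 1e-6), tol = tol)$root
}

#' Stable stationary allele frequencies of a single locus
#'
#' With the trait mean at the optimum, the stationary frequencies of a
#' locus solve a cubic: frequency 1/2 is the only stable solution for
#' effects below the threshold, while above it the two stable roots are
#' \eqn{(1 \pm \sqrt{1 - m})/2} with \eqn{m = (\hat\gamma/\gamma)^2}.
#'
#' @param effect positive allelic effect \eqn{\gamma}.
#' @param threshold nonnegative threshold \eqn{\hat\gamma}.
#' @return Numeric vector of stable stationary frequencies (length 1
#'   below threshold, 2 at or above it; the boundary is degenerate with
#'   both roots at 1/2).
#' @export
stationary_freq_roots <- function(effect, threshold) {
  stopifnot(effect > 0, threshold >= 0)
  if (effect < threshold) return(0.5)
  m <- (threshold / effect)^2
  r <- sqrt(1 - m)
  c((1 - r) / 2, (1 + r) / 2)
}
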