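logit <- function(p) log(p) - log1p(-p)
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Constant-variance decay of the mean deviation
#'
#' During the directional phase after an optimum shift, treating the
#' genetic variance as frozen at its initial value \eqn{c_2(0)} gives
#' exponential relaxation of the mean deviation:
#' \deqn{\Delta c_1(t) = \Delta c_1(0)\, e^{-c_2(0) s t},}
#' with characteristic time \eqn{1/(s\,c_2(0))}. Valid when most effects
#' are small, so the variance barely changes while the mean adapts.
#'
#' @param init_mean_dev \eqn{\Delta c_1(0)}, initial mean deviation.
#' @param sel_coeff selection coefficient `s`.
#' @param init_variance initial genetic variance \eqn{c_2(0) > 0}.
#' @param t nonnegative time (generations); vectorized.
#' @return \eqn{\Delta c_1(t)}.
#' @export
mean_dev_constant_variance <- function(init_mean_dev, sel_coeff,
                                       init_variance, t) {
  stopifnot(init_variance > 0, sel_coeff > 0, all(t >= 0))
  init_mean_dev * exp(-init_variance * sel_coeff * t)
}

#' Allele-frequency trajectory in the constant-variance phase
#'
#' Closed-form solution of the directional-selection-only dynamics
#' \eqn{\partial p/\partial t = -s\gamma p q \Delta c_1(t)} with
#' \eqn{\Delta c_1(t)} from [mean_dev_constant_variance()]:
#' \deqn{p(t) = \frac{p_0}{p_0 + q_0 \exp\left[\frac{\gamma\,\Delta
#'   c_1(0)}{c_2(0)} (1 - e^{-c_2(0) s t})\right]}.}
#' Evaluated on the logit scale, so large exponents do not overflow. At
#' \eqn{t \to \infty} the frequency saturates (it does not reach the
#' stationary roots; stabilizing selection takes over after the
#' crossover time).
#'
#' @param init_freq initial frequency \eqn{p_0 \in [0, 1]}.
#' @param effect allelic effect \eqn{\gamma > 0} of the locus.
#' @inheritParams mean_dev_constant_variance
#' @return \eqn{p(t) \in [0, 1]}; vectorized over `t`.
#' @export
freq_constant_variance <- function(init_freq, effect, init_mean_dev,
                                   sel_coeff, init_variance, t) {
  stopifnot(init_freq >= 0, init_freq <= 1, effect > 0, init_variance > 0)
  if (init_freq == 0 || init_freq == 1) return(rep(init_freq, length(t)))
  shift <- effect * init_mean_dev / init_variance *
    (1 - exp(-init_variance * sel_coeff * t))
  inv_logit(logit(init_freq) - shift)
}

#' Crossover time between directional and stabilizing phases
#'
#' The smallest `t` at which \eqn{|\Delta c_1(t)|/|\Delta c_1(0)|}
#' reaches `ratio_threshold` under the constant-variance decay:
#' \deqn{t_\times = \frac{-\ln(\mathrm{ratio})}{s\,c_2(0)}.}
#' The default `exp(-3)` leaves a 5 percent residual deviation, matching
#' the order-of-magnitude definition \eqn{t_\times \sim (s c_2(0))^{-1}}.
#'
#' @inheritParams mean_dev_constant_variance
#' @param ratio_threshold value in `(0, 1)`.
#' @return Crossover time in generations.
#' @export
crossover_time <- function(sel_coeff, init_variance,
                           ratio_threshold = exp(-3)) {
  stopifnot(ratio_threshold > 0, ratio_threshold < 1,
            sel_coeff > 0, init_variance > 0)
  -log(ratio_threshold) / (sel_coeff * init_variance)
}

#' Long-term allele-frequency relaxation after the crossover
#'
#' Once the mean deviation is negligible, each locus relaxes
#' independently toward its stationary root. With
#' \eqn{m = (\hat\gamma/\gamma)^2} and starting value
#' \eqn{p_\times = p(t_\times)}, the closed-form solution (for a
#' vanishing residual mean deviation) is
#' \deqn{p^{(\pm)}(t) = \frac{1}{2}\left(1 \pm
#'   \sqrt{\frac{1 - m}{1 - M(t)}}\right), \quad
#'   M(t) = \frac{4 p_\times^2 - 4 p_\times + m}{(2 p_\times - 1)^2}
#'   \, e^{-s \gamma^2 (1 - m)(t - t_\times)/2},}
#' taking the `+` branch when \eqn{p_\times > 1/2}. As
#' \eqn{t \to \infty} it converges to \eqn{(1 \pm \sqrt{1-m})/2} for
#' \eqn{m < 1} and to 1/2 for \eqn{m > 1}.
#'
#' @param freq_at_crossover frequency at the crossover time.
#' @param effect allelic effect \eqn{\gamma} of the locus.
#' @param threshold effect threshold \eqn{\hat\gamma}.
#' @param sel_coeff selection coefficient `s`.
#' @param t time (generations), `>= t_x`; vectorized.
#' @param t_x crossover time.
#' @return \eqn{p(t) \in [0, 1]}.
#' @export
freq_long_term <- function(freq_at_crossover, effect, threshold, sel_coeff,
                           t, t_x = 0) {
  stopifnot(all(t >= t_x), effect > 0, threshold >= 0)
  p0 <- freq_at_crossover
  m <- (threshold / effect)^2
  if (m == 1 || p0 == 0.5) return(rep(0.5, length(t)))
  m_big <- 4 * p0^2 - 4 * p0 + m
  m_t <- m_big / (2 * p0 - 1)^2 *
    exp(-sel_coeff * effect^2 * (1 - m) * (t - t_x) / 2)
  branch <- if (p0 > 0.5) 1 else -1
  0.5 * (1 + branch * sqrt((1 - m) / (1 - m_t)))
}

#' Long-term relaxation with a nonzero residual mean deviation
#'
#' Numerically integrates the single-locus stabilizing-phase dynamics
#' \deqn{\frac{\partial p}{\partial t} = -\frac{s}{2}\gamma^2 p q
#'   \left(1 - 2p + \frac{2\Delta c_1^*}{\gamma}\right) + \mu(1 - 2p)}
#' from \eqn{p(t_\times)}, holding the residual mean deviation
#' \eqn{\Delta c_1^*} fixed. With `residual_mean_dev = 0` this agrees
#' with the closed form [freq_long_term()]; the small nonzero stationary
#' residual observed in the full model shifts the late-time frequency
#' and tracks the full dynamics more closely.
#'
#' @inheritParams freq_long_term
#' @param mut_prob mutation probability \eqn{\mu}.
#' @param residual_mean_dev fixed \eqn{\Delta c_1^*}.
#' @param rtol relative tolerance of the adaptive integration.
#' @return \eqn{p(t)}; vectorized over sorted `t`.
#' @export
freq_long_term_ode <- function(freq_at_crossover, effect, threshold,
                               sel_coeff, t, t_x = 0,
                               residual_mean_dev = 0,
                               mut_prob = sel_coeff * threshold^2 / 8,
                               rtol = 1e-8) {
  stopifnot(all(t >= t_x))
  rhs <- function(tt, p) {
    -sel_coeff / 2 * effect^2 * p * (1 - p) *
      (1 - 2 * p + 2 * residual_mean_dev / effect) +
      mut_prob * (1 - 2 * p)
  }
  ts <- sort(unique(c(t_x, t)))
  ps <- numeric(length(ts))
  ps[1] <- freq_at_crossover
  for (i in seq_along(ts)[-1])
    ps[i] <- rk45_integrate(rhs, ps[i - 1], ts[i - 1], ts[i], rtol = rtol)
  ps[match(t, ts)]
}

#' Focal large-effect locus for the sweep approximation
#'
#' When most effects are large, the short-term response to an optimum
#' shift is dominated by the largest-effect locus whose allele is
#' initially rare (for a negative initial mean deviation). Its dynamics
#' close on a cubic one-locus equation with composite parameter
#' \deqn{\alpha = \frac{\Gamma + 2\Delta c_1(0)}{2\Gamma} - P_0.}
#'
#' @param effect focal-locus effect \eqn{\Gamma > 0}.
#' @param init_freq initial frequency \eqn{P_0 \in (0, 1)}.
#' @param init_mean_dev initial mean deviation \eqn{\Delta c_1(0)}
#'   (pre-shift mean minus new optimum).
#' @param init_mean,init_variance initial cumulants \eqn{c_1(0)},
#'   \eqn{c_2(0)} of the whole trait (used by
#'   [single_locus_cumulants()]).
#' @return An object of class `"large_locus_model"` with the fields
#'   above plus `alpha`.
#' @examples
#' large_locus_model(0.776, 3.3e-4, init_mean_dev = 7.8e-5 - 1.5)$alpha
#' @export
large_locus_model <- function(effect, init_freq, init_mean_dev,
                              init_mean = NA_real_,
                              init_variance = NA_real_) {
  stopifnot(effect > 0, init_freq >= 0, init_freq <= 1)
  structure(list(effect = effect, init_freq = init_freq,
                 init_mean_dev = init_mean_dev, init_mean = init_mean,
                 init_variance = init_variance,
                 alpha = large_locus_alpha(effect, init_freq,
                                           init_mean_dev)),
            class = "large_locus_model")
}

#' @export
print.large_locus_model <- function(x, ...) {
  cat(sprintf("Focal large locus: Gamma = %g, P0 = %g, alpha = %.4g\n",
              x$effect, x$init_freq, x$alpha))
  invisible(x)
}

#' Composite sweep parameter of the one-locus approximation
#'
#' \eqn{\alpha = (\Gamma + 2\Delta c_1(0))/(2\Gamma) - P_0}. Large
#' negative \eqn{\alpha} (optimum shift much larger than the effect)
#' makes the sweep logistic with rate \eqn{s\Gamma^2|\alpha|}.
#'
#' @param effect \eqn{\Gamma > 0}.
#' @param init_freq \eqn{P_0}.
#' @param init_mean_dev \eqn{\Delta c_1(0)}.
#' @return \eqn{\alpha}.
#' @export
large_locus_alpha <- function(effect, init_freq, init_mean_dev) {
  stopifnot(effect > 0)
  (effect + 2 * init_mean_dev) / (2 * effect) - init_freq
}

#' Very-short-time logistic growth of a focal allele
#'
#' While the mean deviation is still near its initial value the focal
#' frequency follows
#' \eqn{P(t) = [1 + (Q_0/P_0) e^{\Gamma \Delta c_1(0) s t}]^{-1}}; for a
#' negative initial deviation the allele frequency grows toward one.
#'
#' @param model a [large_locus_model()].
#' @param sel_coeff selection coefficient `s`.
#' @param t time (generations); vectorized.
#' @return \eqn{P(t)}.
#' @export
freq_short_time <- function(model, sel_coeff, t) {
  stopifnot(inherits(model, "large_locus_model"))
  p0 <- model$init_freq
  if (p0 == 0 || p0 == 1) return(rep(p0, length(t)))
  inv_logit(logit(p0) - model$effect * model$init_mean_dev * sel_coeff * t)
}

# Log residual of the implicit sweep solution, monotone in P along the
# trajectory; obtained by partial fractions of the cubic ODE:
#   (1+a) ln(P/P0) - a ln(Q/Q0) - ln((P+a)/(P0+a)) = -s G^2 a (1+a) t
large_locus_implicit_residual <- function(P, model, sel_coeff, t) {
  a <- model$alpha; P0 <- model$init_freq; G <- model$effect
  (1 + a) * (log(P) - log(P0)) - a * (log1p(-P) - log1p(-P0)) -
    (log(abs(P + a)) - log(abs(P0 + a))) +
    sel_coeff * G^2 * a * (1 + a) * t
}

#' Implicit solution of the one-locus sweep equation
#'
#' The closed one-locus dynamics
#' \eqn{\partial P/\partial t = -s\Gamma^2 P(1-P)(P+\alpha)} admit the
#' implicit solution
#' \deqn{\frac{(P/P_0)^{1+\alpha}}{(Q/Q_0)^{\alpha}} =
#'   e^{-s\Gamma^2\alpha(1+\alpha)t}\,\frac{P+\alpha}{P_0+\alpha},}
#' which is solved for \eqn{P(t)} by monotone bracketing of the
#' log-residual within the invariant interval containing \eqn{P_0}
#' (bounded by 0, 1, and the interior fixed point \eqn{-\alpha} when
#' \eqn{\alpha \in (-1, 0)}). All factors are evaluated in log space so
#' large negative \eqn{\alpha} does not overflow.
#'
#' @inheritParams freq_short_time
#' @param tol absolute tolerance of the bracketing root find.
#' @return \eqn{P(t) \in (0, 1)}; vectorized over `t`.
#' @export
large_locus_freq_implicit <- function(model, sel_coeff, t, tol = 1e-10) {
  stopifnot(inherits(model, "large_locus_model"))
  a <- model$alpha; P0 <- model$init_freq
  if (a == 0 || a == -1)
    stop("alpha in {0, -1}: degenerate case, integrate the ODE instead")
  # direction of motion at P0 and the invariant bracket around it
  drift0 <- -(P0 + a)            # sign of dP/dt at P0 (times positive factor)
  eps <- 1e-15
  if (a > -1 && a < 0 && P0 < -a) {
    lo <- P0 * (1 - 1e-12); hi <- -a - eps * abs(a)
  } else if (a > -1 && a < 0 && P0 > -a) {
    lo <- -a + eps * abs(a); hi <- P0 * (1 + 1e-12)
  } else if (drift0 > 0) {
    lo <- P0 * (1 - 1e-12); hi <- 1 - 1e-15
  } else {
    lo <- 1e-30; hi <- P0 * (1 + 1e-12)
  }
  vapply(t, function(tt) {
    if (tt == 0) return(P0)
    f <- function(P) large_locus_implicit_residual(P, model, sel_coeff, tt)
    flo <- f(lo); fhi <- f(hi)
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
      stop(sprintf(paste0("implicit sweep solution not bracketed at t=%g: ",
                          "f(%.3g)=%.3g, f(%.3g)=%.3g"), tt, lo, flo, hi, fhi))
    uniroot(f, c(lo, hi), tol = tol)$root
  }, numeric(1))
}

#' Direct integration of the one-locus sweep equation
#'
#' Adaptive integration of
#' \eqn{\partial P/\partial t = -s\Gamma^2 P(1-P)(P+\alpha)} from
#' \eqn{P_0}; the independent cross-check on
#' [large_locus_freq_implicit()].
#'
#' @inheritParams freq_short_time
#' @param rtol relative tolerance of the integration.
#' @return \eqn{P(t)}; vectorized over sorted `t`.
#' @export
large_locus_freq_ode <- function(model, sel_coeff, t, rtol = 1e-8) {
  stopifnot(inherits(model, "large_locus_model"), all(t >= 0))
  a <- model$alpha; G <- model$effect
  rhs <- function(tt, P) -sel_coeff * G^2 * P * (1 - P) * (P + a)
  ts <- sort(unique(c(0, t)))
  ps <- numeric(length(ts)); ps[1] <- model$init_freq
  for (i in seq_along(ts)[-1])
    ps[i] <- rk45_integrate(rhs, ps[i - 1], ts[i - 1], ts[i], rtol = rtol)
  ps[match(t, ts)]
}

#' Logistic limit of the one-locus sweep
#'
#' For large negative \eqn{\alpha} the implicit solution reduces to a
#' logistic sweep
#' \eqn{P(t) = [1 + (Q_0/P_0) e^{-s\Gamma^2|\alpha|t}]^{-1}} with rate
#' \eqn{s\Gamma^2|\alpha|}; for an optimum shift much larger than
#' \eqn{\Gamma} the allele fixes on a time scale of order
#' \eqn{(s\Gamma z_f)^{-1}}.
#'
#' @inheritParams freq_short_time
#' @return \eqn{P(t)}.
#' @export
large_locus_freq_logistic <- function(model, sel_coeff, t) {
  stopifnot(inherits(model, "large_locus_model"))
  p0 <- model$init_freq
  if (p0 == 0 || p0 == 1) return(rep(p0, length(t)))
  inv_logit(logit(p0) + sel_coeff * model$effect^2 * abs(model$alpha) * t)
}

#' Trait cumulants of the one-locus approximation
#'
#' Approximates the whole-trait mean and variance by the focal locus's
#' contribution on top of the initial values:
#' \deqn{c_1(t) \approx 2\Gamma(P - P_0) + c_1(0), \qquad
#'       c_2(t) \approx 2\Gamma^2(P Q - P_0 Q_0) + c_2(0).}
#' The variance rises transiently (maximal at \eqn{P = 1/2}) and returns
#' near its initial value once the sweep completes.
#'
#' @param model a [large_locus_model()] with `init_mean` and
#'   `init_variance` set.
#' @param P focal frequency (vectorized).
#' @return List with `mean` and `variance`.
#' @export
single_locus_cumulants <- function(model, P) {
  stopifnot(inherits(model, "large_locus_model"), all(P >= 0), all(P <= 1))
  G <- model$effect; P0 <- model$init_freq
  list(mean = 2 * G * (P - P0) + model$init_mean,
       variance = 2 * G^2 * (P * (1 - P) - P0 * (1 - P0)) +
         model$init_variance)
}

#' Pick the focal locus of the sweep approximation
#'
#' For a negative initial mean deviation the dynamics are dominated by
#' the largest-effect locus, tie-broken by lowest initial frequency (for
#' a positive deviation, by highest frequency). The rule is
#' unconditional; whether the selected locus actually sweeps is for the
#' caller to judge.
#'
#' @param state a [population_state()].
#' @param sign_of_mean_dev -1 or +1, sign of \eqn{\Delta c_1(0)}.
#' @return Integer locus index.
#' @export
select_focal_locus <- function(state, sign_of_mean_dev = -1) {
  stopifnot(inherits(state, "population_state"),
            sign_of_mean_dev %in% c(-1, 1))
  if (length(state$freqs) == 0) stop("empty state")
  tie <- if (sign_of_mean_dev < 0) state$freqs else -state$freqs
  order(-state$effects, tie)[1]
}
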