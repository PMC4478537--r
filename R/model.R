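#' Model parameters for the multilocus recursion
#'
#' Bundles the constants of the deterministic model: the number of
#' biallelic loci \eqn{\ell}, the strength \eqn{s} of stabilizing
#' selection (curvature of the quadratic fitness function per squared
#' trait unit), the per-generation probability \eqn{\mu} of symmetric
#' mutation between the + and - allele, and the current position of the
#' phenotypic optimum.
#'
#' @param n_loci positive integer, number of loci \eqn{\ell}.
#' @param sel_coeff positive real, selection coefficient \eqn{s}.
#' @param mut_prob real in `[0, 1/2)`, symmetric mutation probability
#'   \eqn{\mu}.
#' @param optimum real, phenotypic optimum (pre-shift `z_o` or
#'   post-shift `z_f`).
#' @return An object of class `"model_params"`.
#' @examples
#' model_params(n_loci = 50, sel_coeff = 0.02, mut_prob = 5e-5, optimum = 0.5)
#' @export
model_params <- function(n_loci, sel_coeff, mut_prob, optimum = 0) {
  stopifnot(length(n_loci) == 1L, n_loci >= 1, n_loci == as.integer(n_loci))
  if (!is.numeric(sel_coeff) || sel_coeff <= 0)
    stop("`sel_coeff` must be a positive real (s > 0)")
  if (!is.numeric(mut_prob) || mut_prob < 0 || mut_prob >= 0.5)
    stop("`mut_prob` must satisfy 0 <= mu < 1/2")
  stopifnot(is.finite(optimum))
  structure(list(n_loci = as.integer(n_loci), sel_coeff = sel_coeff,
                 mut_prob = mut_prob, optimum = optimum),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Multilocus stabilizing-selection model\n")
  cat(sprintf("  loci:      %d\n  s:         %g\n  mu:        %g\n  optimum:   %g\n",
              x$n_loci, x$sel_coeff, x$mut_prob, x$optimum))
  cat(sprintf("  gamma_hat: %g  (effect scale 2*sqrt(2*mu/s))\n",
              gamma_hat(x$mut_prob, x$sel_coeff)))
  invisible(x)
}

#' Population state: per-locus allele frequencies and effects
#'
#' The + allele at locus i has frequency `freqs[i]` and contributes
#' `+effects[i]` to the trait; the - allele contributes `-effects[i]`.
#' All effects are positive by the sign convention that absorbs the
#' allelic sign into the allele labels.
#'
#' @param freqs numeric vector of + allele frequencies in `[0, 1]`.
#' @param effects numeric vector of positive allelic effects
#'   \eqn{\gamma_i}, same length as `freqs`.
#' @param generation nonnegative integer generation counter.
#' @return An object of class `"population_state"`.
#' @export
population_state <- function(freqs, effects, generation = 0L) {
  if (length(freqs) != length(effects))
    stop("`freqs` and `effects` differ in length")
  if (length(freqs) < 1L) stop("state must contain at least one locus")
  if (any(!is.finite(freqs)) || any(freqs < 0) || any(freqs > 1))
    stop("all frequencies must lie in [0, 1]")
  if (any(!is.finite(effects)) || any(effects <= 0))
    stop("all effects must be strictly positive")
  stopifnot(generation >= 0)
  structure(list(freqs = as.numeric(freqs), effects = as.numeric(effects),
                 generation = as.integer(generation)),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("Population state: %d loci, generation %d\n",
              length(x$freqs), x$generation))
  cat(sprintf("  mean effect %.4g, mean frequency %.4g\n",
              mean(x$effects), mean(x$freqs)))
  invisible(x)
}

#' Trait cumulants of a population state
#'
#' Under linkage equilibrium the cumulants of the trait distribution are
#' sums over loci:
#' \deqn{c_1 = \sum_i \gamma_i (p_i - q_i), \quad
#'       c_2 = 2 \sum_i \gamma_i^2 p_i q_i, \quad
#'       c_3 = 2 \sum_i \gamma_i^3 (q_i - p_i) p_i q_i,}
#' with \eqn{q_i = 1 - p_i}. The mean deviation \eqn{\Delta c_1 = c_1 -}
#' optimum drives directional selection.
#'
#' @param state a [population_state()].
#' @param optimum real, phenotypic optimum used for the mean deviation.
#' @return An object of class `"trait_cumulants"`: a list with elements
#'   `mean`, `variance`, `skewness`, `mean_dev`.
#' @examples
#' st <- population_state(freqs = rep(0.5, 4), effects = c(0.1, 0.2, 0.3, 0.4))
#' trait_cumulants(st, optimum = 0)
#' @export
trait_cumulants <- function(state, optimum = 0) {
  stopifnot(inherits(state, "population_state"))
  p <- state$freqs; q <- 1 - p; g <- state$effects
  g2 <- g * g    # explicit products keep parity with the compiled kernel
  c1 <- sum(g * (p - q))
  c2 <- 2 * sum(g2 * p * q)
  c3 <- 2 * sum(g2 * g * (q - p) * p * q)
  structure(list(mean = c1, variance = c2, skewness = c3,
                 mean_dev = c1 - optimum),
            class = "trait_cumulants")
}

#' @export
print.trait_cumulants <- function(x, ...) {
  cat(sprintf("c1 = %.6g, c2 = %.6g, c3 = %.6g, mean deviation = %.6g\n",
              x$mean, x$variance, x$skewness, x$mean_dev))
  invisible(x)
}

#' Mean population fitness
#'
#' For a Gaussian-like trait distribution under the quadratic fitness
#' function \eqn{w(z) = 1 - (s/2)(z - z_o)^2}, the population mean
#' fitness is \eqn{\bar w = 1 - (s/2)(c_2 + \Delta c_1^2)}, which for
#' small `s` is written in the canonical exponential form
#' \eqn{\exp\{-(s/2)(c_2 + \Delta c_1^2)\}}. Maximum fitness (one) is
#' attained exactly when the population sits at the optimum with zero
#' genetic variance.
#'
#' @param cumulants a [trait_cumulants()] object.
#' @param params a [model_params()] object (only `sel_coeff` is used).
#' @param form `"exponential"` (canonical) or `"quadratic"` (auxiliary
#'   weak-selection form, not guaranteed positive for extreme states).
#' @return Scalar mean fitness; the exponential form lies in `(0, 1]`.
#' @export
mean_fitness <- function(cumulants, params,
                         form = c("exponential", "quadratic")) {
  stopifnot(inherits(cumulants, "trait_cumulants"),
            inherits(params, "model_params"))
  form <- match.arg(form)
  load_ <- cumulants$variance + cumulants$mean_dev^2
  if (form == "exponential") exp(-params$sel_coeff / 2 * load_)
  else 1 - params$sel_coeff / 2 * load_
}

# Shared driver around the compiled recursion kernel.
evolve_kernel <- function(state, params, max_gen, tol = -1,
                          record_every = 1L, record_freqs = FALSE) {
  stopifnot(inherits(state, "population_state"),
            inherits(params, "model_params"))
  .cpp_evolve(state$freqs, state$effects, params$sel_coeff, params$mut_prob,
              params$optimum, as.integer(max_gen), tol,
              as.integer(record_every), record_freqs)
}

#' Advance the population by one generation
#'
#' Applies the synchronous recursion
#' \deqn{p_i(t+1) = p_i(t) - \frac{s \gamma_i^2}{2} p_i q_i
#'   \left(\frac{2\Delta c_1}{\gamma_i} + q_i - p_i\right) + \mu (q_i - p_i),}
#' with the mean deviation \eqn{\Delta c_1} evaluated once from the input
#' state for all loci. Frequencies are clamped to `[0, 1]`; a clamp, or
#' any raw increment exceeding 0.5 in magnitude, indicates parameters
#' outside the weak-selection regime and raises a warning.
#'
#' @param state a [population_state()].
#' @param params a [model_params()].
#' @return The next [population_state()] (generation incremented);
#'   attribute `"n_clamped"` carries the clamp count.
#' @export
step_state <- function(state, params) {
  res <- evolve_kernel(state, params, max_gen = 1L)
  if (res$n_big_steps > 0)
    warning("per-generation frequency increment exceeded 0.5: ",
            "parameters are outside the model's weak-selection regime")
  if (res$n_clamped > 0)
    warning(sprintf("%d frequencies clamped to [0,1]", res$n_clamped))
  out <- population_state(res$p, state$effects, state$generation + 1L)
  attr(out, "n_clamped") <- res$n_clamped
  out
}

#' Simulate a trajectory of the full model
#'
#' Iterates [step_state()] for `n_gen` generations, recording trait
#' cumulants (and optionally full frequency snapshots) every
#' `record_every` generations, always including the initial and final
#' generation. Deterministic given its inputs.
#'
#' @inheritParams step_state
#' @param n_gen nonnegative integer, number of generations.
#' @param record_every positive integer record stride.
#' @param record_freqs logical, keep per-locus frequency snapshots at
#'   recorded generations.
#' @return A list of class `"psm_trajectory"`:
#' \describe{
#'   \item{trajectory}{data frame with columns `generation`, `c1`, `c2`,
#'     `c3`, `mean_dev`, `mean_fitness`.}
#'   \item{state}{final [population_state()].}
#'   \item{freq_snapshots}{matrix (records x loci) if requested.}
#'   \item{n_clamped}{number of clamping events over the run.}
#' }
#' @export
simulate_trajectory <- function(state, params, n_gen, record_every = 1L,
                                record_freqs = FALSE) {
  stopifnot(n_gen >= 0, record_every >= 1)
  res <- evolve_kernel(state, params, max_gen = n_gen,
                       record_every = record_every,
                       record_freqs = record_freqs)
  rec <- as.data.frame(res$records)
  rec$generation <- rec$generation + state$generation
  rec$mean_dev <- rec$c1 - params$optimum
  rec$mean_fitness <- exp(-params$sel_coeff / 2 * (rec$c2 + rec$mean_dev^2))
  out <- list(trajectory = rec,
              state = population_state(res$p, state$effects,
                                       state$generation + res$generations),
              n_clamped = res$n_clamped,
              n_big_steps = res$n_big_steps,
              params = params)
  if (record_freqs) out$freq_snapshots <- res$freq_snapshots
  class(out) <- "psm_trajectory"
  out
}

#' @export
print.psm_trajectory <- function(x, ...) {
  n <- nrow(x$trajectory)
  cat(sprintf("Trajectory: %d records over generations %d..%d, %d loci\n",
              n, x$trajectory$generation[1], x$trajectory$generation[n],
              length(x$state$freqs)))
  cat(sprintf("  final c1 = %.6g, c2 = %.6g, mean_dev = %.6g\n",
              x$trajectory$c1[n], x$trajectory$c2[n], x$trajectory$mean_dev[n]))
  invisible(x)
}

#' Equilibrate the population to a stationary state
#'
#' Iterates the recursion until the largest per-locus frequency change in
#' a generation falls below `tol`, or `max_gen` is reached. In the
#' stationary state small-effect loci sit at frequency 1/2 and
#' large-effect loci near one of the two stable roots; the stationary
#' mean deviation is generally small but nonzero when the optimum is not
#' exactly attainable.
#'
#' @inheritParams step_state
#' @param tol positive convergence tolerance on `max |p(t+1) - p(t)|`.
#' @param max_gen maximum number of generations.
#' @return List with `state` (final [population_state()]), `converged`
#'   flag, `residual_mean_dev` (stationary \eqn{\Delta c_1^*}),
#'   `generations` run, and `n_clamped`.
#' @export
equilibrate_state <- function(state, params, tol = 1e-12, max_gen = 1e6) {
  stopifnot(tol > 0, max_gen >= 0)
  # already stationary to tolerance: report convergence at t = 0
  probe <- evolve_kernel(state, params, max_gen = 1L)
  if (max(abs(probe$p - state$freqs)) < tol) {
    return(list(state = state, converged = TRUE,
                residual_mean_dev = trait_cumulants(state, params$optimum)$mean_dev,
                generations = 0L, n_clamped = 0))
  }
  res <- evolve_kernel(state, params, max_gen = max_gen, tol = tol,
                       record_every = max(1L, as.integer(max_gen)))
  final <- population_state(res$p, state$effects,
                            state$generation + res$generations)
  list(state = final, converged = res$converged,
       residual_mean_dev = trait_cumulants(final, params$optimum)$mean_dev,
       generations = res$generations, n_clamped = res$n_clamped)
}
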