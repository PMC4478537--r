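#' Effect-size threshold separating small from large effects
#'
#' The stationary structure of the model is organized by the scale
#' \deqn{\hat\gamma = 2\sqrt{2\mu/s}:}
#' a locus with effect below \eqn{\hat\gamma} has the single stable
#' stationary frequency 1/2, while a locus above it has two stable
#' stationary frequencies near fixation.
#'
#' @param mut_prob nonnegative mutation probability \eqn{\mu} (or a
#'   [model_params()] object, in which case `sel_coeff` is ignored).
#' @param sel_coeff positive selection coefficient \eqn{s}.
#' @return The threshold \eqn{\hat\gamma \ge 0} (0 when `mut_prob` is 0,
#'   in which case every effect is classified large).
#' @examples
#' gamma_hat(5e-5, 0.02)  # 0.1414
#' gamma_hat(1e-5, 0.1)   # 0.0283
#' @export
gamma_hat <- function(mut_prob, sel_coeff) {
  if (inherits(mut_prob, "model_params")) {
    sel_coeff <- mut_prob$sel_coeff
    mut_prob <- mut_prob$mut_prob
  }
  if (!is.numeric(sel_coeff) || sel_coeff <= 0)
    stop("`sel_coeff` must be positive")
  if (mut_prob < 0) stop("`mut_prob` must be nonnegative")
  2 * sqrt(2 * mut_prob / sel_coeff)
}

#' Configuration of the gamma distribution of allelic effects
#'
#' Effect sizes are modeled as draws from a gamma distribution
#' \eqn{p(\gamma) \propto \gamma^{k-1} e^{-k\gamma/\bar\gamma}} with
#' shape `k` and mean \eqn{\bar\gamma} (scale \eqn{\bar\gamma/k}): it is
#' L-shaped for `k < 1`, exponential at `k = 1`, and increasingly narrow
#' and bell-shaped as `k` grows. The derived threshold \eqn{\hat\gamma}
#' and ratio \eqn{\gamma_r = \hat\gamma/\bar\gamma} position the
#' distribution relative to the small/large effect boundary.
#'
#' @param shape positive gamma shape parameter `k`.
#' @param mean_effect positive mean effect \eqn{\bar\gamma}.
#' @param threshold effect threshold \eqn{\hat\gamma}; either give it
#'   directly or supply `params` to derive it as [gamma_hat()].
#' @param params optional [model_params()] used to derive `threshold`.
#' @return An object of class `"effect_config"` with fields `shape`,
#'   `mean_effect`, `threshold`, `ratio`.
#' @examples
#' effect_config(shape = 1, mean_effect = 0.1, threshold = 0.063)
#' @export
effect_config <- function(shape, mean_effect, threshold = NULL, params = NULL) {
  if (!is.numeric(shape) || shape <= 0) stop("`shape` (k) must be positive")
  if (!is.numeric(mean_effect) || mean_effect <= 0)
    stop("`mean_effect` must be positive")
  if (is.null(threshold)) {
    if (is.null(params)) stop("give either `threshold` or `params`")
    threshold <- gamma_hat(params)
  }
  if (threshold < 0) stop("`threshold` must be nonnegative")
  structure(list(shape = shape, mean_effect = mean_effect,
                 threshold = threshold, ratio = threshold / mean_effect),
            class = "effect_config")
}

#' @export
print.effect_config <- function(x, ...) {
  cat(sprintf("Gamma effect distribution: k = %g, mean = %g\n", x$shape,
              x$mean_effect))
  cat(sprintf("  threshold gamma_hat = %g, ratio gamma_r = %g\n",
              x$threshold, x$ratio))
  invisible(x)
}

#' Sample an effect-size vector
#'
#' Draws `n_loci` i.i.d. effects from the gamma distribution of an
#' [effect_config()] (shape `k`, scale \eqn{\bar\gamma/k}), reproducibly
#' under `seed`.
#'
#' @param config an [effect_config()].
#' @param n_loci positive integer number of draws.
#' @param seed integer seed (NULL to use the current RNG stream).
#' @return Numeric vector of positive effects.
#' @export
sample_effects <- function(config, n_loci, seed = NULL) {
  stopifnot(inherits(config, "effect_config"), n_loci >= 1)
  with_seed(seed, rgamma(n_loci, shape = config$shape,
                         scale = config$mean_effect / config$shape))
}

#' Classify effects as small or large
#'
#' An effect is small when it lies below the threshold \eqn{\hat\gamma}
#' (the measure-zero boundary case is classified small, for
#' determinism). The empirical fraction of small effects is the
#' realized counterpart of the distributional fraction `f_s`
#' ([frac_small_gamma()]).
#'
#' @param effects numeric vector of effects.
#' @param threshold nonnegative threshold \eqn{\hat\gamma}.
#' @return List with `small_mask` (logical), `n_large` (integer), and
#'   `frac_small` (real in `[0, 1]`).
#' @export
classify_effects <- function(effects, threshold) {
  stopifnot(threshold >= 0)
  small <- effects <= threshold
  n_large <- sum(!small)
  list(small_mask = small, n_large = as.integer(n_large),
       frac_small = 1 - n_large / length(effects))
}

#' Initial state with uniform random frequencies
#'
#' Draws independent uniform frequencies on (0, 1) for each locus. The
#' expected initial trait mean is zero; its typical magnitude is of
#' order \eqn{\bar\gamma\sqrt{\ell}} (sd \eqn{\sqrt{\sum\gamma_i^2/3}}).
#'
#' @param effects numeric vector of positive effects.
#' @param seed integer seed (NULL to use the current RNG stream).
#' @return A [population_state()] at generation 0.
#' @export
initial_state_uniform <- function(effects, seed = NULL) {
  population_state(with_seed(seed, runif(length(effects))), effects)
}

#' Initial state equilibrated to a pre-shift optimum
#'
#' Builds the stationary population for an optimum `params$optimum`
#' (typically the small pre-shift value `z_o`). In `"analytic"` mode the
#' per-locus stationary roots for a vanishing mean deviation are used
#' directly: frequency 1/2 for effects below \eqn{\hat\gamma}, and one of
#' the two stable roots \eqn{(1 \pm \sqrt{1 - (\hat\gamma/\gamma_i)^2})/2}
#' chosen equiprobably under `seed` for effects above it. In `"numeric"`
#' mode a seeded uniform state is relaxed to stationarity with
#' [equilibrate_state()]. The analytic state assumes the stationary mean
#' deviation is zero, which holds to high accuracy when `|z_o|` is tiny
#' relative to the trait range.
#'
#' @param effects numeric vector of positive effects.
#' @param params a [model_params()] whose `optimum` is the pre-shift
#'   optimum `z_o`.
#' @param mode `"analytic"` or `"numeric"`.
#' @param seed integer seed for the branch choice (analytic) or the
#'   uniform start (numeric).
#' @param tol,max_gen numeric-mode equilibration controls.
#' @return A [population_state()] at generation 0.
#' @export
initial_state_equilibrated <- function(effects, params,
                                       mode = c("analytic", "numeric"),
                                       seed = NULL, tol = 1e-12,
                                       max_gen = 1e6) {
  stopifnot(inherits(params, "model_params"))
  mode <- match.arg(mode)
  ghat <- gamma_hat(params)
  if (mode == "analytic") {
    large <- effects > ghat
    p <- rep(0.5, length(effects))
    if (any(large)) {
      root_hi <- (1 + sqrt(1 - (ghat / effects[large])^2)) / 2
      up <- with_seed(seed, rbinom(sum(large), 1L, 0.5) == 1L)
      p[large] <- ifelse(up, root_hi, 1 - root_hi)
    }
    population_state(p, effects)
  } else {
    st <- initial_state_uniform(effects, seed)
    eq <- equilibrate_state(st, params, tol = tol, max_gen = max_gen)
    if (!eq$converged)
      warning("numeric equilibration did not converge within `max_gen`")
    population_state(eq$state$freqs, effects)
  }
}

#' Read or write an effect vector as plain text
#'
#' One effect per line; lines starting with `#` are comments.
#'
#' @param path file path.
#' @return `read_effects_file()` returns a numeric vector.
#' @export
read_effects_file <- function(path) {
  x <- scan(path, what = numeric(), comment.char = "#", quiet = TRUE)
  if (length(x) == 0) stop("no effects found in ", path)
  if (any(x <= 0)) stop("effects file contains non-positive values")
  x
}

#' @rdname read_effects_file
#' @param effects numeric vector of effects to write.
#' @param header optional comment lines (written with a leading `#`).
#' @export
write_effects_file <- function(effects, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(paste0("# ", header), con)
  writeLines(format(effects, digits = 17, scientific = TRUE, trim = TRUE), con)
  invisible(path)
}
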