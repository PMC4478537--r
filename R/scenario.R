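#' Scenario configuration for an optimum-shift experiment
#'
#' Bundles everything needed to reproduce a run of the full model:
#' model constants, the effect distribution (or a file of effects), the
#' initial-condition mode, the pre- and post-shift optima, run length,
#' and the three independent seed streams (effect draw, initial
#' frequencies, branch choice for analytic equilibration). Identical
#' configurations produce byte-identical outputs.
#'
#' @param n_loci,sel_coeff,mut_prob model constants (see
#'   [model_params()]).
#' @param shape,mean_effect gamma effect distribution (ignored when
#'   `effects_file` is given).
#' @param effects_file optional path to a one-effect-per-line text file.
#' @param init one of `"uniform"`, `"equilibrated-analytic"`,
#'   `"equilibrated-numeric"`.
#' @param z_o pre-shift optimum (the optimum the initial state is
#'   equilibrated to).
#' @param z_f post-shift optimum.
#' @param shift_gen generations simulated at `z_o` before the shift.
#' @param n_gen generations simulated after the shift.
#' @param record_every record stride (generations).
#' @param eq_tol,eq_max_gen numeric-equilibration controls.
#' @param seed_effects,seed_freqs,seed_branch integer seeds for the
#'   three random choices.
#' @return An object of class `"scenario_config"`.
#' @export
scenario_config <- function(n_loci, sel_coeff, mut_prob,
                            shape = 1, mean_effect = NULL,
                            effects_file = NULL,
                            init = c("equilibrated-analytic", "uniform",
                                     "equilibrated-numeric"),
                            z_o = 0, z_f = 0, shift_gen = 0L,
                            n_gen = 1000L, record_every = 1L,
                            eq_tol = 1e-12, eq_max_gen = 1e6,
                            seed_effects = 1L, seed_freqs = 2L,
                            seed_branch = 3L) {
  init <- match.arg(init)
  bad <- character()
  if (!(is.numeric(n_loci) && length(n_loci) == 1 && n_loci >= 1))
    bad <- c(bad, "n_loci")
  if (!(is.numeric(sel_coeff) && sel_coeff > 0)) bad <- c(bad, "sel_coeff")
  if (!(is.numeric(mut_prob) && mut_prob >= 0 && mut_prob < 0.5))
    bad <- c(bad, "mut_prob")
  if (is.null(effects_file)) {
    if (!(is.numeric(shape) && shape > 0)) bad <- c(bad, "shape")
    if (!(is.numeric(mean_effect) && mean_effect > 0))
      bad <- c(bad, "mean_effect")
  } else if (!file.exists(effects_file)) bad <- c(bad, "effects_file")
  if (!is.finite(z_o)) bad <- c(bad, "z_o")
  if (!is.finite(z_f)) bad <- c(bad, "z_f")
  if (!(n_gen >= 0)) bad <- c(bad, "n_gen")
  if (!(record_every >= 1)) bad <- c(bad, "record_every")
  if (length(bad))
    stop("invalid scenario configuration field(s): ",
         paste(bad, collapse = ", "))
  structure(list(n_loci = as.integer(n_loci), sel_coeff = sel_coeff,
                 mut_prob = mut_prob, shape = shape,
                 mean_effect = mean_effect, effects_file = effects_file,
                 init = init, z_o = z_o, z_f = z_f,
                 shift_gen = as.integer(shift_gen),
                 n_gen = as.integer(n_gen),
                 record_every = as.integer(record_every),
                 eq_tol = eq_tol, eq_max_gen = eq_max_gen,
                 seed_effects = as.integer(seed_effects),
                 seed_freqs = as.integer(seed_freqs),
                 seed_branch = as.integer(seed_branch)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Optimum-shift scenario\n")
  cat(sprintf("  l = %d, s = %g, mu = %g (gamma_hat = %.4g)\n", x$n_loci,
              x$sel_coeff, x$mut_prob, gamma_hat(x$mut_prob, x$sel_coeff)))
  if (is.null(x$effects_file))
    cat(sprintf("  effects: gamma(k = %g, mean = %g), seed %d\n", x$shape,
                x$mean_effect, x$seed_effects))
  else cat(sprintf("  effects: file %s\n", x$effects_file))
  cat(sprintf("  init %s at z_o = %g; shift to z_f = %g; %d generations\n",
              x$init, x$z_o, x$z_f, x$n_gen))
  invisible(x)
}

#' Bundled scenario presets
#'
#' Named parameter regimes matching the package's reference figures:
#' `"fig1a"`/`"fig1b"` (stationary-variance sweeps at \eqn{\ell = 1000}
#' with \eqn{\bar\gamma = 0.04, \hat\gamma = 0.08} and
#' \eqn{\bar\gamma = 0.1, \hat\gamma = 0.05}), `"fig2"` (small-effects
#' shift experiment: \eqn{\ell = 50}, `s` = 0.02, \eqn{\mu = 5\times
#' 10^{-5}}, exponential effects with mean 0.05, shift from
#' \eqn{z_o = -0.0012} to \eqn{z_f = 0.5}), and `"fig4"` (large-effects
#' shift: \eqn{\ell = 20}, `s` = 0.1, \eqn{\mu = 10^{-5}}, mean effect
#' 0.2, shift from \eqn{z_o = 7.8\times 10^{-5}} to \eqn{z_f = 1.5}).
#'
#' @param name optional preset name; omit to get the full named list.
#' @return A [scenario_config()] (or named list of them).
#' @export
bundled_scenarios <- function(name = NULL) {
  presets <- list(
    # gamma_hat = 0.08 via mu = s*ghat^2/8 with s = 0.02
    fig1a = scenario_config(n_loci = 1000, sel_coeff = 0.02,
                            mut_prob = 0.02 * 0.08^2 / 8, shape = 1,
                            mean_effect = 0.04, init = "uniform",
                            n_gen = 0L, seed_effects = 11L,
                            seed_freqs = 12L, seed_branch = 13L),
    fig1b = scenario_config(n_loci = 1000, sel_coeff = 0.02,
                            mut_prob = 0.02 * 0.05^2 / 8, shape = 1,
                            mean_effect = 0.1, init = "uniform",
                            n_gen = 0L, seed_effects = 21L,
                            seed_freqs = 22L, seed_branch = 23L),
    fig2 = scenario_config(n_loci = 50, sel_coeff = 0.02, mut_prob = 5e-5,
                           shape = 1, mean_effect = 0.05,
                           init = "equilibrated-analytic",
                           z_o = -0.0012, z_f = 0.5, n_gen = 4000L,
                           record_every = 5L, seed_effects = 31L,
                           seed_freqs = 32L, seed_branch = 33L),
    fig4 = scenario_config(n_loci = 20, sel_coeff = 0.1, mut_prob = 1e-5,
                           shape = 1, mean_effect = 0.2,
                           init = "equilibrated-analytic",
                           z_o = 7.8e-5, z_f = 1.5, n_gen = 400L,
                           record_every = 1L, seed_effects = 41L,
                           seed_freqs = 42L, seed_branch = 43L))
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop("unknown scenario preset: ", name, " (available: ",
         paste(names(presets), collapse = ", "), ")")
  presets[[name]]
}

scenario_effects <- function(config) {
  if (!is.null(config$effects_file)) read_effects_file(config$effects_file)
  else sample_effects(effect_config(config$shape, config$mean_effect,
                                    threshold = gamma_hat(config$mut_prob,
                                                          config$sel_coeff)),
                      config$n_loci, seed = config$seed_effects)
}

scenario_initial_state <- function(config, effects) {
  params_o <- model_params(length(effects), config$sel_coeff,
                           config$mut_prob, optimum = config$z_o)
  switch(config$init,
         "uniform" = initial_state_uniform(effects, config$seed_freqs),
         "equilibrated-analytic" =
           initial_state_equilibrated(effects, params_o, "analytic",
                                      seed = config$seed_branch),
         "equilibrated-numeric" =
           initial_state_equilibrated(effects, params_o, "numeric",
                                      seed = config$seed_freqs,
                                      tol = config$eq_tol,
                                      max_gen = config$eq_max_gen))
}

#' Run an optimum-shift scenario
#'
#' Builds the effect vector and initial state, optionally simulates at
#' the pre-shift optimum, applies the optimum shift, simulates the
#' response, and assembles a summary combining simulated quantities with
#' their theory-layer counterparts (threshold \eqn{\hat\gamma},
#' closed-form stationary variance, default crossover time, and the
#' focal-locus sweep parameter \eqn{\alpha}).
#'
#' @param config a [scenario_config()].
#' @param out_prefix optional path prefix; when given, writes
#'   `<prefix>_trajectory.tsv`, `<prefix>_summary.json`, and (with
#'   `record_freqs`) `<prefix>_freqs.tsv`.
#' @param record_freqs keep per-locus frequency snapshots.
#' @return List with `trajectory` (the post-shift
#'   [simulate_trajectory()] result), `summary` (named list as written
#'   to JSON), and `state` (final population state).
#' @export
run_scenario <- function(config, out_prefix = NULL, record_freqs = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  effects <- scenario_effects(config)
  state <- scenario_initial_state(config, effects)
  ghat <- gamma_hat(config$mut_prob, config$sel_coeff)

  if (config$shift_gen > 0) {
    params_o <- model_params(length(effects), config$sel_coeff,
                             config$mut_prob, optimum = config$z_o)
    pre <- simulate_trajectory(state, params_o, config$shift_gen,
                               record_every = config$record_every)
    state <- pre$state
  }
  params_f <- model_params(length(effects), config$sel_coeff,
                           config$mut_prob, optimum = config$z_f)
  cum0 <- trait_cumulants(state, config$z_f)
  run <- simulate_trajectory(state, params_f, config$n_gen,
                             record_every = config$record_every,
                             record_freqs = record_freqs)
  final_cum <- trait_cumulants(run$state, config$z_f)

  theory <- NULL
  focal <- NULL
  cls <- classify_effects(effects, ghat)
  if (is.null(config$effects_file)) {
    sv <- stationary_variance_gamma(
      effect_config(config$shape, config$mean_effect, threshold = ghat),
      config$n_loci)
    theory <- list(stationary_variance = sv$total,
                   stationary_variance_small = sv$from_small,
                   stationary_variance_large = sv$from_large,
                   frac_small_expected = sv$frac_small)
  }
  j <- select_focal_locus(state, if (cum0$mean_dev < 0) -1 else 1)
  focal <- list(locus_index = j, effect = effects[j],
                init_freq = state$freqs[j],
                alpha = large_locus_alpha(effects[j], state$freqs[j],
                                          cum0$mean_dev))
  t_x <- if (cum0$variance > 0)
    crossover_time(config$sel_coeff, cum0$variance) else NA_real_

  summary <- list(
    config = unclass(config),
    gamma_hat = ghat,
    n_large_realized = cls$n_large,
    frac_small_realized = cls$frac_small,
    init_cumulants = unclass(cum0),
    crossover_time_default = t_x,
    theory = theory,
    focal_locus = focal,
    final_cumulants = unclass(final_cum),
    residual_mean_dev = final_cum$mean_dev,
    mean_fitness_final = mean_fitness(final_cum, params_f),
    generations = run$state$generation,
    n_clamped = run$n_clamped)

  if (!is.null(out_prefix)) {
    write_trajectory_tsv(run, paste0(out_prefix, "_trajectory.tsv"))
    write_json_file(summary, paste0(out_prefix, "_summary.json"))
    if (record_freqs)
      write_freq_snapshots_tsv(run, paste0(out_prefix, "_freqs.tsv"))
  }
  invisible(list(trajectory = run, summary = summary, state = run$state))
}

#' Rebuild a scenario configuration from a summary JSON
#'
#' A summary written by [run_scenario()] embeds its configuration;
#' reading it back yields a [scenario_config()] that reproduces the
#' identical run.
#'
#' @param path path to a `*_summary.json` file.
#' @return A [scenario_config()].
#' @export
config_from_summary <- function(path) {
  s <- read_json_file(path)
  cf <- s$config
  scenario_config(n_loci = cf$n_loci, sel_coeff = cf$sel_coeff,
                  mut_prob = cf$mut_prob, shape = cf$shape,
                  mean_effect = cf$mean_effect,
                  effects_file = cf$effects_file, init = cf$init,
                  z_o = cf$z_o, z_f = cf$z_f, shift_gen = cf$shift_gen,
                  n_gen = cf$n_gen, record_every = cf$record_every,
                  eq_tol = cf$eq_tol, eq_max_gen = cf$eq_max_gen,
                  seed_effects = cf$seed_effects,
                  seed_freqs = cf$seed_freqs, seed_branch = cf$seed_branch)
}
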