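# Shared fixture builders. All fixtures are generated in code under
# fixed seeds; nothing is read from disk.

# The small-effects optimum-shift regime (50 loci, exponential effects
# with mean 0.05, shift 0 -> 0.5): gamma_hat = 0.1414, most effects small.
fig2_params <- function(optimum = 0.5) {
  model_params(n_loci = 50, sel_coeff = 0.02, mut_prob = 5e-5,
               optimum = optimum)
}

fig2_state <- function(seed = 31, branch_seed = seed + 1000) {
  pr <- fig2_params()
  eff <- sample_effects(effect_config(1, 0.05, params = pr), 50, seed = seed)
  initial_state_equilibrated(eff, fig2_params(-0.0012), mode = "analytic",
                             seed = branch_seed)
}

# The large-effects regime (20 loci, mean effect 0.2, gamma_hat = 0.028,
# shift ~0 -> 1.5): nearly all effects large.
fig4_params <- function(optimum = 1.5) {
  model_params(n_loci = 20, sel_coeff = 0.1, mut_prob = 1e-5,
               optimum = optimum)
}

# A deterministic mixed-effects state (no RNG): effects straddle the
# threshold, frequencies at the stationary roots with balanced branches
# so the trait mean is exactly zero.
root_state <- function(threshold = 0.1) {
  eff <- c(0.05, 0.08, 0.2, 0.2, 0.4, 0.4)
  p <- numeric(length(eff))
  for (i in seq_along(eff)) {
    r <- stationary_freq_roots(eff[i], threshold)
    p[i] <- if (length(r) == 1) r else r[1 + i %% 2]
  }
  population_state(p, eff)
}

expect_close <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol),
              label = sprintf("max |%s - %s| = %.3g <= %.3g",
                              deparse(substitute(actual)),
                              deparse(substitute(expected)),
                              max(abs(actual - expected)), tol))
}
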