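test_that("constant-variance decay and crossover time follow the closed forms", {
  expect_equal(mean_dev_constant_variance(-0.5, 0.02, 0.0967, 0), -0.5)
  # e-folding at t = 1/(s c2(0))
  expect_equal(mean_dev_constant_variance(-0.5, 0.02, 0.0967,
                                          1 / (0.02 * 0.0967)),
               -0.5 / exp(1))
  expect_equal(crossover_time(0.02, 0.0967, exp(-1)), 1 / (0.02 * 0.0967))
  # default threshold e^-3 in the small-effects reference regime
  expect_equal(crossover_time(0.02, 0.0967), 1551.19, tolerance = 1e-4)
  expect_equal(crossover_time(0.02, 0.0967 / 2),
               2 * crossover_time(0.02, 0.0967))
})

test_that("constant-variance frequency solves the directional-phase ODE", {
  p0 <- 0.3; g <- 0.1; dc0 <- -0.5; s <- 0.02; c2 <- 0.0967
  expect_equal(freq_constant_variance(p0, g, dc0, s, c2, 0), p0)
  # no directional pressure: frequency static
  expect_equal(freq_constant_variance(p0, g, 0, s, c2, c(10, 1e4)),
               rep(p0, 2))
  # saturation limit as t -> infinity
  expect_equal(freq_constant_variance(p0, g, dc0, s, c2, 1e9),
               p0 / (p0 + (1 - p0) * exp(g * dc0 / c2)), tolerance = 1e-12)
  # numerical time-derivative equals -s g p q dc1(t)
  for (t in c(5, 200, 1500)) {
    h <- 0.05
    num <- (freq_constant_variance(p0, g, dc0, s, c2, t + h) -
              freq_constant_variance(p0, g, dc0, s, c2, t - h)) / (2 * h)
    p <- freq_constant_variance(p0, g, dc0, s, c2, t)
    ana <- -s * g * p * (1 - p) *
      mean_dev_constant_variance(dc0, s, c2, t)
    expect_equal(num, ana, tolerance = 1e-6)
  }
  # overflow-safe for extreme exponents
  expect_equal(freq_constant_variance(1e-6, 5, -50, 0.1, 1e-3, 1e4), 1,
               tolerance = 1e-9)
})

test_that("long-term closed form reproduces its initial condition, limits, and ODE", {
  s <- 0.02; ghat <- 0.1414; t_x <- 1500
  for (p_tx in c(0.03, 0.4, 0.62, 0.97)) {
    for (g in c(0.05, 0.25)) {        # m > 1 and m < 1
      m <- (ghat / g)^2
      # exact reproduction at t = t_x
      expect_equal(freq_long_term(p_tx, g, ghat, s, t_x, t_x), p_tx,
                   tolerance = 1e-12)
      # stationary limits
      lim <- freq_long_term(p_tx, g, ghat, s, t_x + 1e7, t_x)
      if (m < 1) {
        want <- if (p_tx > 0.5) (1 + sqrt(1 - m)) / 2 else
          (1 - sqrt(1 - m)) / 2
        expect_equal(lim, want, tolerance = 1e-9)
      } else {
        expect_equal(lim, 0.5, tolerance = 1e-6)
      }
      # agrees with direct integration of the stabilizing-phase ODE
      # (mutation folded through m: mu = s ghat^2 / 8)
      ts <- t_x + c(50, 300, 2000)
      ode <- freq_long_term_ode(p_tx, g, ghat, s, ts, t_x,
                                residual_mean_dev = 0,
                                mut_prob = s * ghat^2 / 8)
      expect_equal(freq_long_term(p_tx, g, ghat, s, ts, t_x), ode,
                   tolerance = 1e-6)
    }
  }
  # degenerate cases
  expect_equal(freq_long_term(0.3, 0.1414, 0.1414, s, 2000, t_x), 0.5)
  expect_equal(freq_long_term(0.5, 0.25, 0.1414, s, 2000, t_x), 0.5)
})

test_that("long-term closed form satisfies the stabilizing-phase ODE pointwise", {
  s <- 0.02; ghat <- 0.1414; g <- 0.25; mu <- s * ghat^2 / 8
  m <- (ghat / g)^2
  for (t in c(100, 500, 3000)) {
    h <- 0.05
    num <- (freq_long_term(0.9, g, ghat, s, t + h) -
              freq_long_term(0.9, g, ghat, s, t - h)) / (2 * h)
    p <- freq_long_term(0.9, g, ghat, s, t)
    ana <- -s / 2 * g^2 * p * (1 - p) * (1 - 2 * p) + mu * (1 - 2 * p)
    expect_equal(num, ana, tolerance = 1e-6)
  }
})

test_that("the sweep parameter alpha matches its defining combination", {
  # reference large-effects regime: effect 0.776, initial frequency
  # 3.3e-4, optimum shift from 7.8e-5 to 1.5
  a <- large_locus_alpha(0.776, 3.3e-4, 7.8e-5 - 1.5)
  expect_equal(a, -1.433219, tolerance = 1e-6)
  expect_equal(round(a, 2), -1.43)
  # boundary between dynamical regimes
  expect_equal(large_locus_alpha(0.4, 0, -0.2), 0)
  expect_equal(large_locus_alpha(0.4, 0.5, 0), 0)
  # constructor stores the consistent alpha
  m <- large_locus_model(0.776, 3.3e-4, 7.8e-5 - 1.5)
  expect_equal(m$alpha, (0.776 + 2 * (7.8e-5 - 1.5)) / (2 * 0.776) - 3.3e-4)
})

test_that("implicit sweep solution equals direct integration across alpha regimes", {
  s <- 0.1; G <- 0.776
  for (a in c(-3, -1.43, -0.5, 0.7)) {
    P0 <- if (a < -1) 3.3e-4 else 0.3
    dc0 <- (2 * (a + P0) - 1) * G / 2      # invert the alpha relation
    m <- large_locus_model(G, P0, dc0)
    expect_equal(m$alpha, a, tolerance = 1e-12)
    ts <- seq(0, 5 / (s * G^2 * max(abs(a), 0.2)), length.out = 25)
    expect_equal(large_locus_freq_implicit(m, s, ts),
                 large_locus_freq_ode(m, s, ts), tolerance = 1e-6)
  }
  # t = 0 identity
  m <- large_locus_model(G, 3.3e-4, -1.5)
  expect_identical(large_locus_freq_implicit(m, s, 0), 3.3e-4)
})

test_that("logistic limit approaches the implicit solution as |alpha| grows", {
  s <- 0.1; G <- 0.776; P0 <- 3.3e-4
  sup_for <- function(a) {
    dc0 <- (2 * (a + P0) - 1) * G / 2
    m <- large_locus_model(G, P0, dc0)
    ts <- seq(0, 3 * log((1 - P0) / P0) / (s * G^2 * abs(a)),
              length.out = 100)
    max(abs(large_locus_freq_implicit(m, s, ts) -
              large_locus_freq_logistic(m, s, ts)))
  }
  sups <- vapply(c(-1.43, -5, -30), sup_for, numeric(1))
  expect_true(all(diff(sups) < 0))     # improves as |alpha| grows
  expect_lt(sups[3], 0.02)             # within 2% for large |alpha|
  # at the reference alpha = -1.43 the logistic is only qualitative
  expect_lt(sups[1], 0.25)

  # logistic midpoint: P = 1/2 at t = ln(Q0/P0) / (s G^2 |alpha|)
  m <- large_locus_model(G, P0, 7.8e-5 - 1.5)
  t_half <- log((1 - P0) / P0) / (s * G^2 * abs(m$alpha))
  expect_equal(t_half, 92.95, tolerance = 1e-3)
  expect_equal(large_locus_freq_logistic(m, s, t_half), 0.5)
  expect_equal(large_locus_freq_logistic(m, s, 0), P0, tolerance = 1e-12)
  expect_equal(large_locus_freq_logistic(m, s, 1e6), 1)
})

test_that("short-time logistic matches the constant-variance solution initially", {
  m <- large_locus_model(0.3, 0.05, -1.2)
  s <- 0.1
  expect_equal(freq_short_time(m, s, 0), 0.05, tolerance = 1e-12)
  expect_equal(freq_short_time(m, s, 1e6), 1)   # dc1(0) < 0 sweeps up
  # first-order agreement in c2(0) s t with the constant-variance form:
  # the logit gap is (g |dc0| s t) * (c2 s t / 2), second order in t
  c2 <- 0.05
  for (t in c(1, 5, 20)) {
    a <- freq_short_time(m, s, t)
    b <- freq_constant_variance(0.05, 0.3, -1.2, s, c2, t)
    gap_bound <- 0.3 * 1.2 * s * t * (c2 * s * t / 2) / 4  # /4: max dp/dlogit
    expect_lt(abs(a - b), gap_bound + 1e-12)
  }
})

test_that("single-locus cumulant approximation has the stated structure", {
  m <- large_locus_model(0.776, 3.3e-4, -1.5, init_mean = 7.8e-5,
                         init_variance = 0.02)
  at0 <- single_locus_cumulants(m, 3.3e-4)
  expect_equal(at0$mean, 7.8e-5)
  expect_equal(at0$variance, 0.02)
  # completed sweep: mean shifted by ~2 Gamma, variance back near the
  # start (short by exactly the lost 2 Gamma^2 P0 Q0 term)
  done <- single_locus_cumulants(m, 1)
  expect_equal(done$mean - 7.8e-5, 2 * 0.776 * (1 - 3.3e-4))
  expect_equal(done$variance, 0.02 - 2 * 0.776^2 * 3.3e-4 * (1 - 3.3e-4))
  expect_equal(done$variance, 0.02, tolerance = 0.02)
  # transient variance maximal at P = 1/2
  ps <- seq(0.05, 0.95, by = 0.05)
  vs <- single_locus_cumulants(m, ps)$variance
  expect_equal(ps[which.max(vs)], 0.5)
})

test_that("focal-locus selection follows the largest-effect lowest-frequency rule", {
  st <- population_state(c(0.9, 3.3e-4, 1.9e-3, 0.5),
                         c(0.3, 0.776, 0.776, 0.1))
  expect_identical(select_focal_locus(st, -1), 2L)
  expect_identical(select_focal_locus(st, +1), 3L)
  # rule is unconditional in the frequency
  st2 <- population_state(c(0.99, 0.95), c(0.5, 0.3))
  expect_identical(select_focal_locus(st2, -1), 1L)
  expect_identical(select_focal_locus(population_state(0.2, 0.1), -1), 1L)
})

test_that("residual-aware long-term ODE tracks the full model better than the closed form", {
  # small-effects shift regime, smallest-effect locus: using the true
  # stationary residual mean deviation improves on the zero-residual
  # closed form after the crossover
  pr <- fig2_params()
  st <- fig2_state(seed = 31, branch_seed = 1031)
  c0 <- trait_cumulants(st, 0.5)
  t_x <- crossover_time(0.02, c0$variance)
  run <- simulate_trajectory(st, pr, 4000, record_every = 5,
                             record_freqs = TRUE)
  eq <- equilibrate_state(run$state, pr, tol = 1e-12)
  ghat <- gamma_hat(pr)
  j <- which.min(st$effects)
  tt <- run$trajectory$generation
  after <- tt >= t_x
  p_tx <- freq_constant_variance(st$freqs[j], st$effects[j], c0$mean_dev,
                                 0.02, c0$variance, t_x)
  p_closed <- freq_long_term(p_tx, st$effects[j], ghat, 0.02, tt[after],
                             t_x)
  p_ode <- freq_long_term_ode(p_tx, st$effects[j], ghat, 0.02, tt[after],
                              t_x, residual_mean_dev = eq$residual_mean_dev,
                              mut_prob = pr$mut_prob)
  p_full <- run$freq_snapshots[after, j]
  expect_lt(max(abs(p_ode - p_full)), max(abs(p_closed - p_full)))
})

test_that("single-locus sweep captures the mean response when one rare large locus dominates", {
  # large-effects regime: when the largest-effect initially-rare locus
  # dominates the next one (effect ratio >= 2) and can cover most of
  # the required mean shift (0.6 <= 2 Gamma / |dc1(0)| <= 1), the
  # one-locus approximation tracks the full-model mean deviation within
  # 15% of |dc1(0)| until its sweep nears completion
  pr0 <- fig4_params(optimum = 7.8e-5)
  pr <- fig4_params(optimum = 1.5)
  checked <- 0L
  for (sd in 41:60) {
    eff <- sample_effects(effect_config(1, 0.2, params = pr), 20, seed = sd)
    st <- initial_state_equilibrated(eff, pr0, seed = sd + 100)
    c0 <- trait_cumulants(st, 1.5)
    if (c0$mean_dev >= 0) next
    rare <- which(st$freqs < 0.5)
    if (length(rare) < 2) next
    o <- rare[order(-eff[rare])]
    cover <- 2 * eff[o[1]] / abs(c0$mean_dev)
    if (eff[o[1]] / eff[o[2]] < 2 || cover < 0.6 || cover > 1) next
    checked <- checked + 1L
    j <- o[1]
    m <- large_locus_model(eff[j], st$freqs[j], c0$mean_dev,
                           init_mean = c0$mean,
                           init_variance = c0$variance)
    run <- simulate_trajectory(st, pr, 400, record_every = 1)
    ts <- run$trajectory$generation
    P <- large_locus_freq_ode(m, 0.1, ts)
    keep <- P <= 0.95
    err <- max(abs((single_locus_cumulants(m, P)$mean[keep] - 1.5) -
                     run$trajectory$mean_dev[keep]))
    expect_lt(err / abs(c0$mean_dev), 0.15)
  }
  expect_gte(checked, 3L)   # the premise occurs in a fair share of draws
})
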