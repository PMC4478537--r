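# Adaptive Cash-Karp Runge-Kutta 4(5) for small ODE systems. No ODE
# solver package is assumed; the systems integrated here are scalar and
# smooth, so a compact embedded RK pair with step-doubling control is
# ample. `f(t, y)` returns dy/dt (same length as y).
rk45_integrate <- function(f, y0, t0, t1, rtol = 1e-8, atol = 1e-12,
                           max_steps = 1e6) {
  if (t1 == t0) return(y0)
  # Cash-Karp tableau
  a <- c(1 / 5, 3 / 10, 3 / 5, 1, 7 / 8)
  b21 <- 1 / 5
  b31 <- 3 / 40;        b32 <- 9 / 40
  b41 <- 3 / 10;        b42 <- -9 / 10;    b43 <- 6 / 5
  b51 <- -11 / 54;      b52 <- 5 / 2;      b53 <- -70 / 27;   b54 <- 35 / 27
  b61 <- 1631 / 55296;  b62 <- 175 / 512;  b63 <- 575 / 13824
  b64 <- 44275 / 110592; b65 <- 253 / 4096
  c5 <- c(37 / 378, 0, 250 / 621, 125 / 594, 0, 512 / 1771)
  c4 <- c(2825 / 27648, 0, 18575 / 48384, 13525 / 55296, 277 / 14336, 1 / 4)

  dir <- sign(t1 - t0)
  t <- t0; y <- y0
  h <- dir * (t1 - t0) / 100 * dir
  h <- dir * abs(h)
  for (iter in seq_len(max_steps)) {
    if (dir * (t + h - t1) > 0) h <- t1 - t
    k1 <- f(t, y)
    k2 <- f(t + a[1] * h, y + h * b21 * k1)
    k3 <- f(t + a[2] * h, y + h * (b31 * k1 + b32 * k2))
    k4 <- f(t + a[3] * h, y + h * (b41 * k1 + b42 * k2 + b43 * k3))
    k5 <- f(t + a[4] * h, y + h * (b51 * k1 + b52 * k2 + b53 * k3 + b54 * k4))
    k6 <- f(t + a[5] * h,
            y + h * (b61 * k1 + b62 * k2 + b63 * k3 + b64 * k4 + b65 * k5))
    y5 <- y + h * (c5[1] * k1 + c5[3] * k3 + c5[4] * k4 + c5[6] * k6)
    y4 <- y + h * (c4[1] * k1 + c4[3] * k3 + c4[4] * k4 + c4[5] * k5 +
                     c4[6] * k6)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (!is.finite(err)) { h <- h / 2; next }
    if (err <= 1) {
      t <- t + h
      y <- y5
      if (dir * (t - t1) >= 0) return(y)
      h <- h * min(5, max(0.2, 0.9 * err^(-0.2)))
    } else {
      h <- h * max(0.2, 0.9 * err^(-0.25))
    }
  }
  stop("rk45_integrate: step limit reached before t1")
}
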