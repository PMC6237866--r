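# Independent numerical oracles, deliberately kept apart from the package's
# own solver paths (deSolve / vectorized Logan).

# Closed-form 1TCM solution for the linear-rise + tri-exponential plasma
# model: piecewise-analytic convolution with the kernel K1 * exp(-k2 t).
oracle_1tcm_closed_form <- function(K1, k2, aif, t) {
  Tp <- aif$peak_time
  P <- aif$peak_value
  A <- aif$amplitudes
  lam <- aif$decay_rates
  c_at <- function(ti) {
    if (ti <= Tp) {
      K1 * P / Tp * (ti / k2 - (1 - exp(-k2 * ti)) / k2^2)
    } else {
      u <- ti - Tp
      c_tp <- K1 * P / Tp * (Tp / k2 - (1 - exp(-k2 * Tp)) / k2^2)
      c_tp * exp(-k2 * u) +
        K1 * sum(A * (exp(-lam * u) - exp(-k2 * u)) / (k2 - lam))
    }
  }
  vapply(t, c_at, numeric(1))
}

# Exact-exponential trapezoidal convolution of a sampled input with
# exp(-theta t); recursive update, no ODE solver involved.
conv_exp <- function(cp, step, theta) {
  e <- exp(-theta * step)
  out <- numeric(length(cp))
  for (i in 2:length(cp))
    out[i] <- out[i - 1] * e + step * (cp[i] + cp[i - 1] * e) / 2
  out
}

# Independent 2TCM tissue curve via the bi-exponential impulse response
# (eigen-decomposition of the rate matrix), frame-averaged like the package.
oracle_2tcm_conv <- function(params, input_fun, schedule, step = 1 / 60) {
  with(params, {
    s <- k2 + k3 + k4
    disc <- sqrt(s^2 - 4 * k2 * k4)
    th1 <- (s - disc) / 2
    th2 <- (s + disc) / 2
    c1 <- K1 * (k3 + k4 - th1) / (th2 - th1)
    c2 <- K1 * (th2 - k3 - k4) / (th2 - th1)
    grid <- seq(0, max(schedule$end), by = step)
    cp <- input_fun(grid)
    tissue <- c1 * conv_exp(cp, step, th1) + c2 * conv_exp(cp, step, th2)
    mids <- petkin::frame_midpoints(schedule)
    avg <- vapply(seq_len(nrow(schedule)), function(k) {
      i0 <- round(schedule$start[k] / step) + 1L
      i1 <- round(schedule$end[k] / step) + 1L
      v <- tissue[i0:i1]
      (sum(v) - (v[1] + v[length(v)]) / 2) * step /
        (schedule$end[k] - schedule$start[k])
    }, numeric(1))
    petkin::tac(mids, avg, label = "oracle")
  })
}

# Monte-Carlo 90% band of the sample R^2 of a simple regression when the
# population R^2 is rho2, via plain bivariate-normal simulation.
r2_band <- function(rho2, n, nrep = 2000, seed = 99) {
  withr::with_seed(seed, {
    r2 <- replicate(nrep, {
      x <- stats::rnorm(n)
      y <- sqrt(rho2) * x + sqrt(1 - rho2) * stats::rnorm(n)
      stats::cor(x, y)^2
    })
    stats::quantile(r2, c(0.05, 0.95))
  })
}
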