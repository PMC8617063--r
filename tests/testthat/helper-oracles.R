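# Independent oracles used across the test files. These deliberately avoid
# the package's own fitting code paths.

# closed-form OLS slope/intercept via the normal equations
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# golden-section minimiser on [lo, hi]
golden_min <- function(f, lo, hi, tol = 1e-12) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (abs(b - a) > tol * (abs(a) + abs(b) + 1e-300)) {
    if (f1 < f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    }
  }
  (a + b) / 2
}

# brute-force Morrison Ki' estimate: log-spaced grid then golden section,
# Ki' in the same unit as It/Et
morrison_grid_oracle <- function(It, fv, Et, lo = 1e-5, hi = 1e3) {
  sse <- function(lki) {
    ki <- exp(lki)
    b <- ki + It - Et
    pred <- (sqrt(b^2 + 4 * ki * Et) - b) / (2 * Et)
    sum((fv - pred)^2)
  }
  grid <- seq(log(lo), log(hi), length.out = 400)
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  lo_i <- grid[max(i - 1, 1)]; hi_i <- grid[min(i + 1, length(grid))]
  exp(golden_min(sse, lo_i, hi_i))
}

# brute-force 4PL: grid over (x0, H) with asymptotes profiled by linear LS
logistic_grid_oracle <- function(conc, y, x0_range, H_range) {
  x <- log10(conc)
  best <- list(sse = Inf)
  for (x0 in seq(x0_range[1], x0_range[2], length.out = 200)) {
    for (H in seq(H_range[1], H_range[2], length.out = 60)) {
      w <- 1 / (1 + 10^(H * (x - x0)))   # weight on A1; (1-w) on A2
      fit <- stats::lm(y ~ w)            # y = A2 + (A1 - A2) w
      sse <- sum(stats::resid(fit)^2)
      if (sse < best$sse) {
        cf <- stats::coef(fit)
        best <- list(sse = sse, x0 = x0, H = H,
                     A2 = unname(cf[1]), A1 = unname(cf[1] + cf[2]))
      }
    }
  }
  best
}

# censored lognormal Hill negative log-likelihood (independent re-derivation)
rt50_nll_oracle <- function(rt50, hill, sigma, records, baseline, cap) {
  mu <- ifelse(records$dose <= 0, baseline,
               baseline + (cap - baseline) / (1 + (rt50 / records$dose)^hill))
  y <- pmin(records$response_time_min, cap)
  ll <- ifelse(records$censored,
               stats::pnorm((log(cap) - log(mu)) / sigma,
                            lower.tail = FALSE, log.p = TRUE),
               stats::dnorm((log(y) - log(mu)) / sigma, log = TRUE) -
                 log(sigma) - log(y))
  -sum(ll)
}

# simulate the 1:1 binding ODE dR/dt = kon*C*(Rmax - R) - koff*R
bli_ode_oracle <- function(kon, koff, Rmax, conc_M, times) {
  deSolve::lsoda(
    y = c(R = 0),
    times = times,
    func = function(t, y, p) list(kon * conc_M * (Rmax - y[1]) - koff * y[1]),
    parms = NULL, rtol = 1e-10, atol = 1e-12)[, "R"]
}

# standard synthetic dilution-series sensorgrams used in several tests
make_bli_panel <- function(kon = 8e5, koff = 1e-3, Rmax = 2,
                           conc_nM = c(20, 6.7, 2.2, 0.74, 0.25, 0.082, 0.027),
                           noise_sd = 0, seed = 1, dt = 5) {
  gen_sensorgrams(sim_spec(
    "sensorgram",
    truth = list(kon = kon, koff = koff, Rmax_nm = Rmax),
    design = list(conc_nM = conc_nM, t_assoc_s = 2400, t_dissoc_s = 3600,
                  dt_s = dt),
    noise_sd = noise_sd, seed = seed))
}
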