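analytic_cwa_trace <- function(dt = 0.1) {
  gen_cwa_trace(sim_spec("cwa_trace",
    truth = list(baseline_pct = 100, drop_pct = 50, midpoint_s = 30,
                 scale_s = 2),
    design = list(duration_s = 60, dt_s = dt)))
}

test_that("cwa_analyze recovers the logistic max-slope identity", {
  r <- cwa_analyze(analytic_cwa_trace())
  expect_equal(r$min1, -50 / (4 * 2), tolerance = 1e-4)
  expect_equal(r$min1_time_s, 30, tolerance = 0.2)
  expect_equal(r$clot_time_s, r$min1_time_s)
  expect_false(r$no_clot)
})

test_that("cwa derivatives match finite differences of the closed form", {
  r <- cwa_analyze(analytic_cwa_trace(dt = 0.05))
  # closed-form first derivative of 100 - 50*logistic((t-30)/2), then
  # numerical differentiation at fine step for orders 2 and 3
  f1 <- function(t) {
    u <- (t - 30) / 2
    -50 / 2 * stats::plogis(u) * (1 - stats::plogis(u))
  }
  g <- seq(20, 40, by = 1e-3)
  h <- 1e-3
  min2_true <- min((f1(g + h) - f1(g - h)) / (2 * h))
  min3_true <- min((f1(g + h) - 2 * f1(g) + f1(g - h)) / h^2)
  expect_lt(abs(r$min2 - min2_true) / abs(min2_true), 5e-3)
  expect_lt(abs(r$min3 - min3_true) / abs(min3_true), 5e-3)
})

test_that("flat traces give an explicit no-clot result", {
  flat <- data.frame(time_s = seq(0, 60, 0.5),
                     transmittance_pct = 100)
  r <- cwa_analyze(flat)
  expect_true(r$no_clot)
  expect_true(is.na(r$min1) && is.na(r$min2) && is.na(r$min3))
  expect_true(is.na(r$clot_time_s))
})

test_that("cwa_analyze and tgt_parameters are time-shift invariant", {
  trc <- analytic_cwa_trace()
  r0 <- cwa_analyze(trc)
  shifted <- transform(trc, time_s = time_s + 17)
  r1 <- cwa_analyze(shifted)
  expect_equal(r1$min1, r0$min1, tolerance = 1e-10)
  expect_equal(r1$min1_time_s - r0$min1_time_s, 17)

  tg <- gen_thrombogram(sim_spec("thrombogram",
    truth = list(LT_min = 3, TTpeak_min = 6, peak_nM = 250, shape = 3),
    design = list(duration_min = 40, dt_min = 0.05)))
  p0 <- tgt_parameters(tg)
  p1 <- tgt_parameters(transform(tg, time_min = time_min + 5))
  expect_equal(p1$LT_min - p0$LT_min, 5, tolerance = 1e-9)
  expect_equal(p1$TTpeak_min - p0$TTpeak_min, 5)
  expect_equal(p1$peak_nM, p0$peak_nM)
  expect_equal(p1$ETP_nM_min, p0$ETP_nM_min, tolerance = 1e-9)
  expect_equal(p1$VI_nM_per_min, p0$VI_nM_per_min, tolerance = 1e-9)
})

triangle_pulse <- function(dt = 0.05) {
  t <- seq(0, 20, by = dt)
  y <- ifelse(t < 2, 0,
              ifelse(t <= 5, 100 * (t - 2), 300 * (20 - t) / 15))
  data.frame(time_min = t, thrombin_nM = pmax(y, 0))
}

test_that("tgt_parameters reproduces triangular-pulse geometry exactly", {
  p <- tgt_parameters(triangle_pulse(), lag_fraction = 0)
  expect_equal(p$LT_min, 2)
  expect_equal(p$TTpeak_min, 5)
  expect_equal(p$peak_nM, 300)
  expect_equal(p$ETP_nM_min, 2700)
  expect_equal(p$VI_nM_per_min, 100)
})

test_that("tgt_parameters scales homogeneously in thrombin amplitude", {
  tp <- triangle_pulse()
  p1 <- tgt_parameters(tp, lag_fraction = 0.1)
  tp2 <- transform(tp, thrombin_nM = 2 * thrombin_nM)
  p2 <- tgt_parameters(tp2, lag_fraction = 0.1)
  expect_equal(p2$peak_nM, 2 * p1$peak_nM)
  expect_equal(p2$ETP_nM_min, 2 * p1$ETP_nM_min)
  expect_equal(p2$VI_nM_per_min, 2 * p1$VI_nM_per_min)
  expect_equal(p2$LT_min, p1$LT_min)    # fraction threshold scales too
  expect_equal(p2$TTpeak_min, p1$TTpeak_min)
  expect_error(tgt_parameters(data.frame(time_min = 1:60,
                                         thrombin_nM = 0)), "no thrombin")
})

test_that("gamma-pulse ETP matches the quadrature oracle and is additive", {
  sp <- sim_spec("thrombogram",
                 truth = list(LT_min = 3, TTpeak_min = 6, peak_nM = 250,
                              shape = 3),
                 design = list(duration_min = 80, dt_min = 0.05))
  tg <- gen_thrombogram(sp)
  p <- tgt_parameters(tg, lag_fraction = 0.01)
  expect_lt(abs(p$ETP_nM_min - attr(tg, "truth")$ETP_nM_min) /
              attr(tg, "truth")$ETP_nM_min, 5e-3)

  # two non-overlapping pulses: areas add within quadrature tolerance
  sp2 <- sim_spec("thrombogram",
                  truth = list(LT_min = 45, TTpeak_min = 48, peak_nM = 120,
                               shape = 4),
                  design = list(duration_min = 80, dt_min = 0.05))
  tg2 <- gen_thrombogram(sp2)
  both <- data.frame(time_min = tg$time_min,
                     thrombin_nM = tg$thrombin_nM + tg2$thrombin_nM)
  etp_sum <- tgt_parameters(tg, lag_fraction = 0.01)$ETP_nM_min +
    tgt_parameters(tg2, lag_fraction = 0.01)$ETP_nM_min
  expect_equal(tgt_parameters(both, lag_fraction = 0.01)$ETP_nM_min,
               etp_sum, tolerance = 1e-9)
})

test_that("TGT parameter recovery holds under 2% amplitude noise", {
  truth <- list(LT_min = 3, TTpeak_min = 6, peak_nM = 250, shape = 3)
  dt <- 0.1
  # reference: the same estimator on the noiseless pulse (the 10%-of-peak
  # lag definition sits after the generator's onset lag by construction)
  ref <- tgt_parameters(gen_thrombogram(sim_spec("thrombogram",
    truth = truth, design = list(duration_min = 60, dt_min = dt))))
  errs <- t(vapply(1:100, function(i) {
    tg <- gen_thrombogram(sim_spec("thrombogram", truth = truth,
                                   design = list(duration_min = 60,
                                                 dt_min = dt),
                                   noise_sd = 0.02 * 250, seed = i))
    p <- tgt_parameters(tg, smooth_window = 5)
    c(lt = abs(p$LT_min - ref$LT_min), tt = abs(p$TTpeak_min - 6),
      peak = abs(p$peak_nM - 250) / 250,
      etp = abs(p$ETP_nM_min - attr(tg, "truth")$ETP_nM_min) /
        attr(tg, "truth")$ETP_nM_min)
  }, numeric(4)))
  expect_lt(stats::median(errs[, "tt"]), dt + 1e-9)
  expect_lt(stats::median(errs[, "peak"]), 0.03)
  expect_lt(stats::median(errs[, "etp"]), 0.03)
  # lag time is threshold-crossing based; allow a few samples of noise slip
  expect_lt(stats::median(errs[, "lt"]), 3 * dt)
})

test_that("fit_loglog matches the power law and the OLS oracle", {
  f <- fit_loglog(c(1, 4, 100), 10 * c(1, 4, 100)^0.5, "TTpeak")
  expect_equal(f$m, 0.5, tolerance = 1e-12)
  expect_equal(f$C, 1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)

  expect_equal(fit_loglog(c(1, 10, 100), rep(7, 3))$m, 0)

  set.seed(5)
  x <- c(0.01, 0.1, 1, 10)
  y <- 10^(0.8 * log10(x) + 0.3 + rnorm(4, 0, 0.05))
  f2 <- fit_loglog(x, y)
  oracle <- ols_oracle(log10(x), log10(y))
  expect_equal(f2$m, unname(oracle["slope"]), tolerance = 1e-12)
  expect_equal(f2$C, unname(oracle["intercept"]), tolerance = 1e-12)

  expect_error(fit_loglog(c(-1, 1, 2), c(1, 2, 3)), "positive")
})

test_that("fold-change normalisation shifts only the log-log intercept", {
  doses <- c(0.01, 0.1, 1)
  vals <- 10^(0.5 * log10(doses) + 1.2)
  raw <- fit_loglog(doses, vals, "peak")
  fc <- fit_loglog(doses, fold_change_series(vals, 4), "peak")
  expect_equal(fc$m, raw$m, tolerance = 1e-12)
  expect_equal(fc$C, raw$C - log10(4), tolerance = 1e-12)
  expect_equal(fold_change_series(10, 10), 1)
  expect_equal(fold_change_series(25, 10), 2.5)
  expect_error(fold_change_series(1, 0), "> 0")
})

test_that("gradient_ratio compares dose-intensity slopes", {
  a <- fit_loglog(c(1, 10, 100), 10^(0.2 * log10(c(1, 10, 100))), "TTpeak")
  b <- fit_loglog(c(1, 10, 100), 10^(0.1 * log10(c(1, 10, 100))), "TTpeak")
  expect_equal(gradient_ratio(a, b), 2, tolerance = 1e-10)
  expect_equal(gradient_ratio(a, a), 1)
  c_fit <- fit_loglog(c(1, 10, 100), 10^(0.1 * log10(c(1, 10, 100))), "LT")
  expect_error(gradient_ratio(a, c_fit), "parameter")

  # four-drug panel with slope truths: extreme cross-ratios as constructed
  slopes <- c(variegin = 0.1, ultravariegin = 0.15, ufh = 0.6,
              bivalirudin = 0.9)
  fits <- lapply(slopes, function(m)
    fit_loglog(c(0.1, 1, 10), 10^(m * log10(c(0.1, 1, 10))), "TTpeak"))
  ratios <- outer(c("ufh", "bivalirudin"), c("variegin", "ultravariegin"),
                  Vectorize(function(i, j) gradient_ratio(fits[[i]],
                                                          fits[[j]])))
  expect_equal(min(ratios), 0.6 / 0.15, tolerance = 1e-9)
  expect_equal(max(ratios), 0.9 / 0.1, tolerance = 1e-9)
})
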