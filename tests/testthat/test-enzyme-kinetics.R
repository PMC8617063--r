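test_that("morrison_velocity reproduces its closed-form limits", {
  # no inhibitor returns vo; stoichiometric titration at Ki' = 0
  expect_equal(morrison_velocity(50, 0, 0.8, vo = 3), 3)
  expect_equal(morrison_velocity(0, 0.8, 0.8), 0)
  expect_equal(morrison_velocity(0, 0.4, 0.8), 0.5)
  # Ki' = It = Et = k for any k gives the golden-ratio value
  for (k in c(1e-3, 1, 42)) {
    expect_equal(morrison_velocity(k, k, k), (sqrt(5) - 1) / 2,
                 tolerance = 1e-12)
  }
  expect_error(morrison_velocity(1, 1, 0), "Et")
})

test_that("morrison_velocity is monotone in It and Ki_prime", {
  set.seed(11)
  for (i in 1:25) {
    Et <- runif(1, 0.1, 5)
    ki <- 10^runif(1, -4, 1)
    It <- sort(runif(8, 0, 5 * Et))
    v_it <- morrison_velocity(ki, It, Et)
    expect_true(all(diff(v_it) <= 1e-12))
    kis <- sort(10^runif(8, -4, 2))
    v_ki <- morrison_velocity(kis, Et / 2, Et)
    expect_true(all(diff(v_ki) >= -1e-12))
    expect_true(all(v_it >= 0 & v_it <= 1 + 1e-12))
  }
})

test_that("estimate_velocity matches the normal-equations oracle", {
  t <- seq(0, 600, by = 5)
  exact <- data.frame(time_s = t, absorbance_au = 0.30 + 0.010 * t / 60)
  v <- estimate_velocity(exact)
  expect_equal(v$v, 0.010, tolerance = 1e-12)
  expect_equal(v$r_squared, 1)

  flat <- data.frame(time_s = t, absorbance_au = rep(0.3, length(t)))
  expect_equal(estimate_velocity(flat)$v, 0)

  set.seed(7)
  noisy <- data.frame(time_s = t,
                      absorbance_au = 0.1 + 0.02 * t / 60 +
                        rnorm(length(t), 0, 0.001))
  v2 <- estimate_velocity(noisy)
  oracle <- ols_oracle(t, noisy$absorbance_au)
  expect_equal(v2$v, unname(oracle["slope"]) * 60, tolerance = 1e-12)

  expect_error(estimate_velocity(exact, window = c(1e4, 2e4)), "window|samples")
  expect_error(estimate_velocity(exact[1:4, ]), "5 samples")
})

test_that("fractional_velocities normalises by the It = 0 reference", {
  vel <- data.frame(It_nM = c(0, 0.4, 0.8), v = c(0.02, 0.02, 0))
  s <- fractional_velocities(vel, Et_nM = 0.8, S_uM = 100)
  expect_s3_class(s, "inhibition_series")
  expect_equal(s$fv, c(1, 1, 0))
  # activation (fractional velocity above 1) is permitted
  act <- fractional_velocities(
    data.frame(It_nM = c(0, 10), v = c(0.02, 0.024)), 0.8, 100)
  expect_equal(act$fv[act$It_nM == 10], 1.2)
  expect_error(fractional_velocities(
    data.frame(It_nM = c(1, 2), v = c(1, 2)), 0.8, 100), "reference")
  expect_error(fractional_velocities(
    data.frame(It_nM = c(0, 1), v = c(0, 1)), 0.8, 100), "> 0")
})

test_that("fit_morrison recovers noiseless truth and matches the grid oracle", {
  Et <- 0.8
  It <- c(0, 0.4, 0.8, 1.2, 1.6)
  fv <- morrison_velocity(0.05, It, Et)   # Ki' = 50 pM
  fit <- fit_morrison(inhibition_series(It, fv, Et, 100))
  expect_lt(abs(fit$Ki_prime_pM - 50) / 50, 1e-6)
  expect_true(fit$tight_binding)   # pM-scale Ki' << 0.8 nM enzyme

  set.seed(23)
  for (i in 1:5) {
    ki <- 10^runif(1, -3, 0.5)
    Et_i <- runif(1, 0.2, 2)
    It_i <- seq(0, 2.5 * Et_i, length.out = 6)
    fv_i <- morrison_velocity(ki, It_i, Et_i)
    fit_i <- fit_morrison(inhibition_series(It_i, fv_i, Et_i, 100))
    oracle <- morrison_grid_oracle(It_i, fv_i, Et_i)
    expect_equal(fit_i$Ki_prime_pM / 1e3, oracle, tolerance = 1e-6)
  }

  expect_error(fit_morrison(inhibition_series(It, rep(0.5, 5), Et, 100)),
               "degenerate")
})

test_that("fitted-vo mode also recovers the generating parameters", {
  Et <- 0.8
  It <- c(0, 0.3, 0.6, 0.9, 1.2, 1.8)
  fv <- morrison_velocity(0.02, It, Et, vo = 0.9)
  fit <- fit_morrison(inhibition_series(It, fv, Et, 100), vo_mode = "fitted")
  expect_equal(fit$vo, 0.9, tolerance = 1e-6)
  expect_lt(abs(fit$Ki_prime_pM - 20) / 20, 1e-5)
})

test_that("ki_from_substrate_series recovers an exact competitive line", {
  # Ki = 4 pM, Km = 100 uM
  S <- c(100, 200, 400)
  kip <- 4 * (1 + S / 100)
  fit <- ki_from_substrate_series(S, kip)
  expect_equal(fit$Ki_pM, 4, tolerance = 1e-12)
  expect_equal(fit$Km_uM, 100, tolerance = 1e-10)
  expect_equal(fit$mode_call, "competitive_consistent")
  expect_equal(fit$linearity_r2, 1, tolerance = 1e-12)
})

test_that("ki_from_substrate_series flags non-competitive patterns", {
  S <- c(100, 200, 300, 400)
  fit <- ki_from_substrate_series(S, rep(6, 4))
  expect_equal(fit$mode_call, "nonlinear")
  expect_true(is.na(fit$Km_uM) || !is.finite(fit$Km_uM))
  expect_error(ki_from_substrate_series(c(100, 100, 100), c(1, 2, 3)),
               "3 substrate levels")
})

test_that("morrison + substrate-series round trip returns the generating Ki", {
  # end-to-end: Eq-style consistency of the apparent and true constants
  Ki_true <- 0.004   # nM = 4 pM
  Km <- 100
  Et <- 0.8
  S_levels <- c(100, 150, 200, 300, 400)
  kip_hat <- vapply(S_levels, function(S) {
    kip <- Ki_true * (1 + S / Km)
    It <- c(0, 0.2, 0.4, 0.8, 1.2, 1.6)
    fv <- morrison_velocity(kip, It, Et)
    fit_morrison(inhibition_series(It, fv, Et, S))$Ki_prime_pM
  }, numeric(1))
  fit <- ki_from_substrate_series(S_levels, kip_hat)
  expect_equal(fit$Ki_pM, 4, tolerance = 1e-5)
  expect_equal(fit$Km_uM, 100, tolerance = 1e-4)
})

test_that("fit_logistic_ic50 recovers truth and matches the grid oracle", {
  conc <- 10^seq(-2, 2, length.out = 9)   # nM
  y <- 100 / (1 + (1.66 / conc)^1)        # A1 = 0, A2 = 100, H = 1
  fit <- fit_logistic_ic50(conc, y)
  expect_lt(abs(fit$IC50 - 1.66) / 1.66, 1e-3)
  # inflection identity
  mid <- fit$A2 + (fit$A1 - fit$A2) / 2
  expect_equal(mid, (fit$A1 + fit$A2) / 2)

  oracle <- logistic_grid_oracle(conc, y, x0_range = c(-0.5, 1),
                                 H_range = c(0.2, 3))
  expect_lt(abs(fit$x0 - oracle$x0), 1e-2)   # within the oracle grid spacing
  expect_lt(abs(fit$H - oracle$H), 5e-2)
  expect_lte(fit$rss, oracle$sse + 1e-10)

  expect_error(fit_logistic_ic50(conc, rep(50, 9)), "constant")
  expect_error(fit_logistic_ic50(c(1, 2, 3), c(1, 2, 3)), "4 dose")
})

test_that("noncompetitive Ki is the IC50 relabelled, surviving round trips", {
  conc <- 10^seq(-1, 2, length.out = 8)
  y <- 100 / (1 + (1.66 / conc)^1.2)
  fit <- fit_logistic_ic50(conc, y)
  nk <- noncompetitive_ki(fit)
  expect_equal(nk$Ki, fit$IC50)
  expect_equal(nk$mode, "noncompetitive")
  # annotation survives serialization
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(Ki = nk$Ki, mode = nk$mode), tmp,
                   row.names = FALSE)
  back <- utils::read.csv(tmp)
  expect_equal(back$Ki, nk$Ki)
  expect_equal(back$mode, "noncompetitive")
})

test_that("percent_inhibition handles inhibition and activation", {
  expect_equal(percent_inhibition(0.02, 0.02), 0)
  expect_equal(percent_inhibition(0, 0.02), 100)
  expect_equal(percent_inhibition(0.024, 0.02), -20)
  expect_error(percent_inhibition(1, 0), "> 0")
})

test_that("selectivity_fold reports the thrombin-panel lower bound", {
  # target active at 0.1 nM; 12 off-targets all below threshold at 100 uM
  offs <- paste0("protease_", 1:12)
  panel <- rbind(
    data.frame(protease_id = "thrombin",
               inhibitor_conc_M = c(1e-10, 1e-9, 1e-8),
               pct_inhibition = c(27, 70, 95)),
    do.call(rbind, lapply(offs, function(p)
      data.frame(protease_id = p,
                 inhibitor_conc_M = c(1e-6, 1e-5, 1e-4),
                 pct_inhibition = c(2, 5, 15)))))
  res <- selectivity_fold(panel, "thrombin", threshold_pct = 20)
  expect_gte(res$fold, 1e6)
  expect_true(res$selective)

  # identical qualifying concentrations give fold 1
  p2 <- data.frame(protease_id = c("a", "b"),
                   inhibitor_conc_M = c(1e-9, 1e-9),
                   pct_inhibition = c(50, 10))
  expect_equal(selectivity_fold(p2, "a")$fold, 1)

  # off-target hit below the target concentration: non-selective
  p3 <- data.frame(protease_id = c("a", "b", "b"),
                   inhibitor_conc_M = c(1e-8, 1e-10, 1e-9),
                   pct_inhibition = c(50, 5, 60))
  r3 <- selectivity_fold(p3, "a")
  expect_lt(r3$fold, 1)
  expect_false(r3$selective)
})

test_that("ki_fold_ratio computes potency folds", {
  expect_equal(ki_fold_ratio(1780, 4.0, "nearest_integer"), 445)
  expect_equal(ki_fold_ratio(3, 3), 1)
  expect_equal(ki_fold_ratio(1660, 4.0, "nearest_integer"), 415)
  expect_error(ki_fold_ratio(-1, 4), "positive")
})

test_that("the bundled peptide table is complete and self-consistent", {
  tab <- peptide_ki_table()
  expect_true(all(c("peptide_id", "sequence", "Ki_pM", "Ki_SE_pM") %in%
                    names(tab)))
  expect_equal(nrow(tab), 14)
  uv <- tab[tab$peptide_id == "ultravariegin", ]
  expect_equal(uv$Ki_pM, 4.0)
  expect_equal(nchar(uv$sequence), 30)   # 30-residue peptide
  # BV001 does not inhibit: recorded as NA
  expect_true(is.na(tab$Ki_pM[tab$peptide_id == "BV001"]))
})
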