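#' Simulation specification for a synthetic assay read-out
#'
#' A `sim_spec` bundles everything a generator needs: the assay kind, the
#' ground-truth model parameters, the sampling design, the noise level in
#' the read-out's native unit, and a seed. A fixed spec produces identical
#' output on every run; per-replicate random sub-streams are derived
#' deterministically from the single seed. Zero-noise generators evaluate
#' exactly the forward models the fitting modules use, so generator truth
#' parameters are directly comparable with fitted estimates.
#'
#' @param assay_kind one of "progress_curve", "inhibition_panel",
#'   "cwa_trace", "thrombogram", "invivo_doseresponse", "sensorgram"
#' @param truth named list of model parameters (units per consuming module)
#' @param design named list: sampling grid (time step + duration, or
#'   dose/concentration lists, replicate count)
#' @param noise_sd additive Gaussian SD in the read-out's native unit
#'   (multiplicative log-scale SD for in-vivo response times)
#' @param seed integer seed
#' @return list of class `sim_spec`
#' @export
sim_spec <- function(assay_kind, truth, design, noise_sd = 0, seed = 1L) {
  assay_kind <- match.arg(assay_kind,
                          c("progress_curve", "inhibition_panel", "cwa_trace",
                            "thrombogram", "invivo_doseresponse",
                            "sensorgram"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(is.list(truth), is.list(design))
  structure(list(assay_kind = assay_kind, truth = truth, design = design,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_spec")
}

# deterministic per-replicate sub-stream: one global seed per spec
sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 7919) %% 2147483629)
}

check_kind <- function(spec, kind) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$assay_kind != kind)
    stop(sprintf("spec has assay_kind '%s', generator expects '%s'",
                 spec$assay_kind, kind))
}

#' Generate chromogenic-substrate progress curves
#'
#' Linear progress curves (absorbance vs time) under Morrison fractional
#' velocities: each inhibitor concentration's slope is
#' v0 * morrison_velocity(Ki', It, Et) plus additive Gaussian noise on the
#' absorbance samples. In competitive mode Ki' is derived from the true Ki
#' and Km as Ki' = Ki (1 + S/Km).
#'
#' Required `truth` fields: `v0_AU_per_min`, `Et_nM`, and either
#' `Ki_prime_pM` or (`Ki_pM`, `Km_uM`) with `mode = "competitive"`;
#' optional `A0` baseline absorbance (default 0.05).
#' Required `design` fields: `It_nM` (vector, should include 0), `S_uM`
#' (scalar or vector), `duration_s`, `dt_s`.
#'
#' @param spec a [sim_spec()] with `assay_kind = "progress_curve"`
#' @return long data frame: `curve_id`, `time_s`, `absorbance_au`, `Et_nM`,
#'   `It_nM`, `S_uM`; attribute `truth` carries the generating parameters
#'   including each curve's true slope
#' @export
gen_progress_curves <- function(spec) {
  check_kind(spec, "progress_curve")
  tr <- spec$truth; dg <- spec$design
  if (dg$dt_s <= 0) stop("dt must be positive")
  if (any(dg$It_nM < 0) || tr$Et_nM <= 0 || any(dg$S_uM <= 0))
    stop("negative or zero concentrations not allowed")
  A0 <- if (is.null(tr$A0)) 0.05 else tr$A0
  tt <- seq(0, dg$duration_s, by = dg$dt_s)
  grid <- expand.grid(It_nM = dg$It_nM, S_uM = dg$S_uM)
  curves <- vector("list", nrow(grid))
  truth_rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    It <- grid$It_nM[i]; S <- grid$S_uM[i]
    ki_prime_pM <- if (!is.null(tr$Ki_prime_pM)) tr$Ki_prime_pM
    else tr$Ki_pM * (1 + S / tr$Km_uM)
    fv <- morrison_velocity(ki_prime_pM / 1e3, It, tr$Et_nM, vo = 1)
    slope <- tr$v0_AU_per_min * fv            # AU/min
    y <- A0 + slope * tt / 60
    if (spec$noise_sd > 0) {
      set.seed(sub_seed(spec$seed, i))
      y <- y + stats::rnorm(length(tt), 0, spec$noise_sd)
    }
    curves[[i]] <- data.frame(curve_id = i, time_s = tt, absorbance_au = y,
                              Et_nM = tr$Et_nM, It_nM = It, S_uM = S)
    truth_rows[[i]] <- data.frame(curve_id = i, It_nM = It, S_uM = S,
                                  Ki_prime_pM = ki_prime_pM,
                                  fractional_velocity = fv,
                                  slope_AU_per_min = slope)
  }
  structure(do.call(rbind, curves),
            truth = c(tr, list(per_curve = do.call(rbind, truth_rows))),
            class = c("progress_curves", "data.frame"))
}

#' Generate a thrombin-generation curve
#'
#' Single-pulse thrombogram built from a gamma-density-shaped pulse shifted
#' by the lag time and rescaled so its maximum equals the requested peak at
#' the requested time-to-peak. The instrument's true output shape is
#' proprietary; the gamma pulse reproduces the lag/rise/decay structure and
#' has a closed-form area, which the generator reports as the true ETP.
#'
#' Required `truth`: `LT_min`, `TTpeak_min` (> LT), `peak_nM` (> 0),
#' `shape` (gamma shape > 1; larger = more symmetric pulse).
#' Required `design`: `duration_min`, `dt_min`.
#'
#' @param spec a [sim_spec()] with `assay_kind = "thrombogram"`
#' @return data frame `time_min`, `thrombin_nM` with attribute `truth`
#'   (including `ETP_nM_min`)
#' @export
gen_thrombogram <- function(spec) {
  check_kind(spec, "thrombogram")
  tr <- spec$truth; dg <- spec$design
  if (tr$TTpeak_min <= tr$LT_min) stop("TTpeak must exceed LT")
  if (tr$peak_nM <= 0) stop("peak must be positive")
  k <- if (is.null(tr$shape)) 3 else tr$shape
  if (k <= 1) stop("gamma shape must exceed 1 for a zero-baseline pulse")
  theta <- (tr$TTpeak_min - tr$LT_min) / (k - 1)   # mode at TTpeak - LT
  tt <- seq(0, dg$duration_min, by = dg$dt_min)
  x <- pmax(tt - tr$LT_min, 0)
  dens <- stats::dgamma(x, shape = k, scale = theta)
  dmax <- stats::dgamma((k - 1) * theta, shape = k, scale = theta)
  y <- tr$peak_nM * dens / dmax
  etp_true <- tr$peak_nM / dmax                     # peak/dmax * integral(1)
  if (spec$noise_sd > 0) {
    # instrument noise rides on the calibrated signal; small negative
    # excursions near the baseline are part of the noise model
    set.seed(sub_seed(spec$seed, 1L))
    y <- y + stats::rnorm(length(y), 0, spec$noise_sd)
  }
  structure(data.frame(time_min = tt, thrombin_nM = y),
            truth = c(tr, list(shape = k, ETP_nM_min = etp_true)),
            class = c("thrombogram", "data.frame"))
}

#' Generate a clot-waveform transmittance trace
#'
#' Monotone-decreasing logistic fall of light transmittance plus additive
#' Gaussian noise, bounded between `baseline - drop` and `baseline`. The
#' noiseless minimum slope is -drop/(4 scale) at the midpoint.
#'
#' Required `truth`: `baseline_pct`, `drop_pct` (<= baseline),
#' `midpoint_s`, `scale_s` (> 0; logistic time scale).
#' Required `design`: `duration_s`, `dt_s`.
#'
#' @param spec a [sim_spec()] with `assay_kind = "cwa_trace"`
#' @return data frame `time_s`, `transmittance_pct` with attribute `truth`
#' @export
gen_cwa_trace <- function(spec) {
  check_kind(spec, "cwa_trace")
  tr <- spec$truth; dg <- spec$design
  if (tr$drop_pct > tr$baseline_pct) stop("drop cannot exceed baseline")
  if (tr$drop_pct < 0) stop("drop must be >= 0")
  tt <- seq(0, dg$duration_s, by = dg$dt_s)
  y <- tr$baseline_pct -
    tr$drop_pct * stats::plogis((tt - tr$midpoint_s) / tr$scale_s)
  if (spec$noise_sd > 0) {
    set.seed(sub_seed(spec$seed, 1L))
    y <- y + stats::rnorm(length(y), 0, spec$noise_sd)
  }
  structure(data.frame(time_s = tt, transmittance_pct = y),
            truth = c(tr, list(min1_true = -tr$drop_pct / (4 * tr$scale_s))),
            class = c("cwa_trace", "data.frame"))
}

#' Generate cap-censored in-vivo dose-response records
#'
#' Latent response times follow a saturating Hill curve between the saline
#' baseline and the observation cap,
#' RT(d) = baseline + (cap - baseline)/(1 + (rt50/d)^hill), with
#' multiplicative log-normal noise (median-preserving: latent * exp(sigma Z)).
#' Draws at or above the cap are recorded at the cap and flagged censored,
#' mirroring the fixed observation window of the animal models.
#'
#' Required `truth`: `baseline_min`, `cap_min` (> baseline), `rt50`,
#' `hill`, `sigma_log` (log-scale SD; `noise_sd` of the spec is ignored for
#' this generator in favour of `sigma_log`).
#' Required `design`: `doses` (vector), `n_per_dose`.
#'
#' @param spec a [sim_spec()] with `assay_kind = "invivo_doseresponse"`
#' @return data frame `subject_id`, `dose`, `response_time_min`, `censored`,
#'   `cap_min` with attribute `truth`
#' @export
gen_invivo_doseresponse <- function(spec) {
  check_kind(spec, "invivo_doseresponse")
  tr <- spec$truth; dg <- spec$design
  if (tr$cap_min <= tr$baseline_min) stop("cap must exceed baseline")
  if (any(dg$doses < 0)) stop("doses must be >= 0")
  rows <- vector("list", length(dg$doses))
  for (i in seq_along(dg$doses)) {
    d <- dg$doses[i]
    latent <- hill_response_time(d, tr$baseline_min, tr$cap_min,
                                 tr$rt50, tr$hill)
    if (tr$sigma_log > 0) {
      set.seed(sub_seed(spec$seed, i))
      t_i <- latent * exp(stats::rnorm(dg$n_per_dose, 0, tr$sigma_log))
    } else {
      t_i <- rep(latent, dg$n_per_dose)
    }
    cen <- t_i >= tr$cap_min * (1 - 1e-9)   # saturating doses hit the cap
    rows[[i]] <- data.frame(
      subject_id = sprintf("d%02d_s%02d", i, seq_len(dg$n_per_dose)),
      dose = d,
      response_time_min = ifelse(cen, tr$cap_min, t_i),
      censored = cen,
      cap_min = tr$cap_min)
  }
  structure(do.call(rbind, rows), truth = tr,
            class = c("invivo_records", "data.frame"))
}

#' Generate a dilution series of 1:1 sensorgrams
#'
#' Wraps [simulate_1to1()] (the exact forward model of the fitting module)
#' for each analyte concentration and adds seeded Gaussian noise.
#'
#' Required `truth`: `kon`, `koff`, `Rmax_nm`.
#' Required `design`: `conc_nM` (vector), `t_assoc_s`, `t_dissoc_s`, `dt_s`.
#'
#' @param spec a [sim_spec()] with `assay_kind = "sensorgram"`
#' @return list of `sensorgram` data frames, one per concentration, with
#'   attribute `truth`
#' @export
gen_sensorgrams <- function(spec) {
  check_kind(spec, "sensorgram")
  tr <- spec$truth; dg <- spec$design
  out <- vector("list", length(dg$conc_nM))
  for (i in seq_along(dg$conc_nM)) {
    s <- simulate_1to1(tr$kon, tr$koff, tr$Rmax_nm, dg$conc_nM[i],
                       t_assoc = dg$t_assoc_s, t_dissoc = dg$t_dissoc_s,
                       dt = dg$dt_s)
    if (spec$noise_sd > 0) {
      set.seed(sub_seed(spec$seed, i))
      s$response_nm <- s$response_nm +
        stats::rnorm(nrow(s), 0, spec$noise_sd)
    }
    out[[i]] <- s
  }
  structure(out,
            truth = c(tr, list(KD_nM = tr$koff / tr$kon * 1e9)))
}
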