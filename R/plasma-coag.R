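#' Clot waveform analysis
#'
#' Differentiates an aPTT light-transmittance trace to the minima of its
#' first three derivatives: min1 (%/s, maximum rate of transmittance fall, a
#' proxy for thrombin activity), min2 (%/s^2, prothrombinase) and min3
#' (%/s^3, tenase). Derivatives are estimated with Savitzky-Golay local
#' polynomial filters (raw finite differences amplify noise); the window and
#' polynomial order are configurable. Clot time is reported as the time of
#' min1, the point of steepest fall. A trace whose total transmittance drop
#' is below `no_clot_drop` yields an explicit no-clot result with all minima
#' `NA` rather than an error.
#'
#' @param trace data frame with columns `time_s` (near-uniformly sampled,
#'   >= 50 points) and `transmittance_pct`
#' @param smooth_window odd Savitzky-Golay window length in samples
#'   (default 21)
#' @param poly_order local polynomial order (default 5; must exceed 3 to
#'   support a third derivative)
#' @param no_clot_drop minimum transmittance drop (%) for a clot call
#' @return list of class `cwa_result`: `clot_time_s`, `min1`, `min1_time_s`,
#'   `min2`, `min2_time_s`, `min3`, `min3_time_s`, `no_clot`
#' @export
cwa_analyze <- function(trace, smooth_window = 21, poly_order = 5,
                        no_clot_drop = 1) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "transmittance_pct") %in% names(trace)))
  t <- trace$time_s
  y <- trace$transmittance_pct
  n <- length(t)
  if (n < 50L) stop("at least 50 samples required")
  if (is.unsorted(t, strictly = TRUE)) stop("time must be strictly increasing")
  dt <- diff(t)
  if (max(dt) / min(dt) > 1.05)
    stop("near-uniform sampling required for derivative filters")
  if (smooth_window %% 2 == 0) smooth_window <- smooth_window + 1
  if (poly_order <= 3) stop("poly_order must exceed 3 for a third derivative")
  if (smooth_window <= poly_order) stop("smooth_window must exceed poly_order")

  if (max(y) - min(y) < no_clot_drop) {
    return(structure(list(clot_time_s = NA_real_,
                          min1 = NA_real_, min1_time_s = NA_real_,
                          min2 = NA_real_, min2_time_s = NA_real_,
                          min3 = NA_real_, min3_time_s = NA_real_,
                          no_clot = TRUE),
                     class = "cwa_result"))
  }

  h <- mean(dt)
  deriv <- function(m) {
    signal::sgolayfilt(y, p = poly_order, n = smooth_window, m = m, ts = h)
  }
  # drop filter edge transients before locating minima
  edge <- smooth_window
  core <- seq(edge + 1L, n - edge)
  d1 <- deriv(1); d2 <- deriv(2); d3 <- deriv(3)
  i1 <- core[which.min(d1[core])]
  i2 <- core[which.min(d2[core])]
  i3 <- core[which.min(d3[core])]
  structure(list(clot_time_s = t[i1],
                 min1 = d1[i1], min1_time_s = t[i1],
                 min2 = d2[i2], min2_time_s = t[i2],
                 min3 = d3[i3], min3_time_s = t[i3],
                 no_clot = FALSE),
            class = "cwa_result")
}

#' Thrombin-generation curve parameters
#'
#' Scalar summaries of a single-pulse thrombogram: peak thrombin (nM),
#' time-to-peak TTpeak (min), lag time LT, endogenous thrombin potential
#' ETP (nM min, trapezoidal area under the curve) and velocity index
#' VI = peak / (TTpeak - LT) (nM/min). The lag time is the first upward
#' crossing (linearly interpolated) of `lag_fraction * peak` (default 0.1);
#' `lag_mode = "threshold"` instead uses a fixed thrombin concentration
#' (`lag_threshold_nM`, default 2 nM), the Thrombinoscope-style variant.
#'
#' Small negative excursions (instrument noise around the calibrated zero
#' baseline) are tolerated and integrated as measured; an optional
#' Savitzky-Golay pre-smoothing (`smooth_window` > 1) stabilises the peak
#' and lag estimates on noisy traces without touching exact geometric
#' inputs when left off.
#'
#' @param curve data frame with columns `time_min` and `thrombin_nM`
#' @param lag_fraction fraction of peak defining the lag time
#' @param lag_mode "fraction" or "threshold"
#' @param lag_threshold_nM absolute threshold for `lag_mode = "threshold"`
#' @param smooth_window odd Savitzky-Golay window (samples); 1 = no smoothing
#' @return list of class `tgt_params`: `LT_min`, `TTpeak_min`, `peak_nM`,
#'   `ETP_nM_min`, `VI_nM_per_min`, `VI_defined`
#' @export
tgt_parameters <- function(curve, lag_fraction = 0.1,
                           lag_mode = c("fraction", "threshold"),
                           lag_threshold_nM = 2, smooth_window = 1) {
  lag_mode <- match.arg(lag_mode)
  stopifnot(is.data.frame(curve),
            all(c("time_min", "thrombin_nM") %in% names(curve)))
  t <- curve$time_min
  y <- curve$thrombin_nM
  if (is.unsorted(t, strictly = TRUE)) stop("time must be strictly increasing")
  if (all(y <= 0)) stop("no thrombin generation in curve")
  if (smooth_window > 1) {
    if (smooth_window %% 2 == 0) smooth_window <- smooth_window + 1
    y <- signal::sgolayfilt(y, p = 2, n = smooth_window)
  }
  ipk <- which.max(y)
  peak <- y[ipk]
  ttpeak <- t[ipk]
  thr <- if (lag_mode == "fraction") lag_fraction * peak else lag_threshold_nM
  above <- which(y > thr)
  if (length(above) == 0L) stop("curve never exceeds the lag threshold")
  i <- above[1]
  LT <- if (i == 1L) t[1] else {
    # linear interpolation of the upward crossing
    t[i - 1] + (thr - y[i - 1]) * (t[i] - t[i - 1]) / (y[i] - y[i - 1])
  }
  etp <- sum(diff(t) * (y[-1] + y[-length(y)])) / 2
  vi_defined <- ttpeak > LT
  structure(list(LT_min = LT, TTpeak_min = ttpeak, peak_nM = peak,
                 ETP_nM_min = etp,
                 VI_nM_per_min = if (vi_defined) peak / (ttpeak - LT)
                 else NA_real_,
                 VI_defined = vi_defined),
            class = "tgt_params")
}

#' Fold change over vehicle control
#'
#' @param values parameter values by dose
#' @param vehicle_value the vehicle-control value (> 0)
#' @return values / vehicle_value
#' @export
fold_change_series <- function(values, vehicle_value) {
  if (vehicle_value <= 0) stop("vehicle value must be > 0")
  values / vehicle_value
}

#' Log-log dose-intensity regression
#'
#' Fits Y = 10^(m log10(X) + C) by ordinary least squares of log10(Y) on
#' log10(X). The slope m measures how fast anticoagulant intensity (a
#' thrombogram or clot-waveform parameter) changes with dose; shallow slopes
#' indicate gradual, titratable dose response.
#'
#' @param doses positive doses/concentrations (>= 3 levels)
#' @param values positive parameter values (raw or fold-change; the choice
#'   shifts only the intercept C)
#' @param parameter_name label, one of "LT", "TTpeak", "peak", "ETP", "VI",
#'   "min1" (free-form allowed)
#' @return list of class `loglog_fit`: `m`, `C`, `r_squared`,
#'   `parameter_name`
#' @export
fit_loglog <- function(doses, values, parameter_name = "parameter") {
  stopifnot(length(doses) == length(values))
  if (any(doses <= 0) || any(values <= 0))
    stop("doses and values must be positive for a log-log fit")
  if (length(unique(doses)) < 3L) stop("at least 3 dose levels required")
  lx <- log10(doses); ly <- log10(values)
  fit <- stats::lm(ly ~ lx)
  tss <- sum((ly - mean(ly))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::resid(fit)^2) / tss
  structure(list(m = unname(stats::coef(fit)[2]),
                 C = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 parameter_name = parameter_name),
            class = "loglog_fit")
}

#' Ratio of dose-intensity gradients between two drugs
#'
#' @param fit_a,fit_b [fit_loglog()] fits of the same parameter
#' @return |m_a| / |m_b|
#' @export
gradient_ratio <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "loglog_fit"), inherits(fit_b, "loglog_fit"))
  if (!identical(fit_a$parameter_name, fit_b$parameter_name))
    stop("gradients compare only within the same parameter")
  if (fit_b$m == 0) stop("reference gradient is zero")
  abs(fit_a$m) / abs(fit_b$m)
}
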