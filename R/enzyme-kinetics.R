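#' Morrison tight-binding velocity
#'
#' Fractional steady-state velocity of an enzyme in the presence of a
#' tight-binding inhibitor. When inhibitor and enzyme concentrations are of
#' the same order, binding depletes the free inhibitor pool and the classical
#' hyperbolic inhibition law no longer applies; the velocity instead follows
#' the quadratic (Morrison) solution of the mass-balance equations:
#'
#' \deqn{v_s = \frac{v_o}{2E_t}\left(\sqrt{(K_i' + I_t - E_t)^2 + 4K_i'E_t}
#'   - (K_i' + I_t - E_t)\right)}
#'
#' All three concentrations must be supplied in the same unit (the result is
#' invariant to that common unit).
#'
#' @param Ki_prime apparent inhibition constant, same unit as `It`/`Et`
#' @param It total inhibitor concentration
#' @param Et total enzyme concentration (> 0)
#' @param vo uninhibited velocity (default 1: fractional velocity)
#' @return steady-state velocity `vs`, in the unit of `vo`; vectorised over
#'   `It` and `Ki_prime`.
#' @examples
#' morrison_velocity(0, It = 0.4, Et = 0.8)      # stoichiometric titration
#' morrison_velocity(1, It = 1, Et = 1)          # (sqrt(5) - 1) / 2
#' @export
morrison_velocity <- function(Ki_prime, It, Et, vo = 1) {
  if (any(Et <= 0)) stop("Et must be > 0")
  if (any(Ki_prime < 0)) stop("Ki_prime must be >= 0")
  if (any(It < 0)) stop("It must be >= 0")
  b <- Ki_prime + It - Et
  (vo / (2 * Et)) * (sqrt(b^2 + 4 * Ki_prime * Et) - b)
}

#' Steady-state velocity from a chromogenic progress curve
#'
#' Ordinary least-squares slope of absorbance against time over a fitting
#' window, reported in AU/min. Fast-binding inhibitors give linear progress
#' curves, so a straight-line fit over the full read (default) is the
#' velocity estimator; `r_squared` is reported as the linearity diagnostic.
#'
#' @param curve data frame with columns `time_s` and `absorbance_au`
#' @param window numeric length-2 time span in seconds (default: full trace)
#' @return list of class `velocity_estimate`: `v` (AU/min), `r_squared`,
#'   `window`, `n`
#' @export
estimate_velocity <- function(curve, window = NULL) {
  stopifnot(is.data.frame(curve),
            all(c("time_s", "absorbance_au") %in% names(curve)))
  t <- curve$time_s
  if (is.unsorted(t, strictly = TRUE)) stop("time must be strictly increasing")
  if (is.null(window)) window <- range(t)
  keep <- t >= window[1] & t <= window[2]
  if (sum(keep) < 5L) stop("fewer than 5 samples in fitting window")
  tt <- t[keep]
  yy <- curve$absorbance_au[keep]
  fit <- stats::lm(yy ~ tt)
  tss <- sum((yy - mean(yy))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::resid(fit)^2) / tss
  structure(list(
    v = unname(stats::coef(fit)[2]) * 60,  # AU/s -> AU/min
    r_squared = r2,
    window = window,
    n = sum(keep)
  ), class = "velocity_estimate")
}

#' Build a fractional-velocity inhibition series
#'
#' Normalises velocities measured at a range of inhibitor concentrations by
#' the uninhibited (It = 0) velocity of the same enzyme/substrate condition.
#' Values above 1 are retained: some cleavage products activate rather than
#' inhibit the amidolytic activity.
#'
#' @param velocities data frame with columns `It_nM` and `v` (AU/min),
#'   containing exactly one `It_nM == 0` reference row
#' @param Et_nM total enzyme concentration, nM
#' @param S_uM substrate concentration, uM
#' @return object of class `inhibition_series`: data frame with columns
#'   `It_nM`, `fv` and attributes `Et_nM`, `S_uM`
#' @export
fractional_velocities <- function(velocities, Et_nM, S_uM) {
  stopifnot(is.data.frame(velocities),
            all(c("It_nM", "v") %in% names(velocities)))
  ref <- velocities$It_nM == 0
  if (sum(ref) != 1L) stop("exactly one It = 0 reference curve required")
  v0 <- velocities$v[ref]
  if (v0 <= 0) stop("uninhibited velocity must be > 0")
  inhibition_series(velocities$It_nM, velocities$v / v0, Et_nM, S_uM)
}

#' Inhibition series constructor
#'
#' @param It_nM inhibitor concentrations, nM (>= 0)
#' @param fv fractional velocities vs/vo (>= 0; > 1 allowed, activation)
#' @param Et_nM enzyme concentration, nM
#' @param S_uM substrate concentration, uM
#' @return data frame of class `inhibition_series`
#' @export
inhibition_series <- function(It_nM, fv, Et_nM, S_uM) {
  stopifnot(length(It_nM) == length(fv), Et_nM > 0, S_uM > 0,
            all(It_nM >= 0), all(fv >= 0))
  out <- data.frame(It_nM = It_nM, fv = fv)
  out <- out[order(out$It_nM), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, Et_nM = Et_nM, S_uM = S_uM,
            class = c("inhibition_series", "data.frame"))
}

#' Fit the Morrison tight-binding equation
#'
#' Nonlinear least-squares estimate of the apparent inhibition constant
#' Ki' from a fractional-velocity series. The fit is performed on
#' log(Ki') to enforce positivity; the standard error is mapped back by the
#' delta method. By default the uninhibited velocity is fixed at the measured
#' It = 0 value (fractional velocity 1); `vo_mode = "fitted"` frees it.
#'
#' @param series an [inhibition_series()]
#' @param vo_mode "fixed" (vo = 1, default) or "fitted"
#' @return list of class `tight_binding_fit`: `Ki_prime_pM`, `Ki_prime_se_pM`,
#'   `vo`, `rss`, `Et_nM`, `S_uM`, `tight_binding` (TRUE when Ki' << Et)
#' @export
fit_morrison <- function(series, vo_mode = c("fixed", "fitted")) {
  vo_mode <- match.arg(vo_mode)
  stopifnot(inherits(series, "inhibition_series"))
  if (nrow(series) < 4L)
    stop("at least 4 points required for a tight-binding fit")
  if (length(unique(series$fv)) == 1L)
    stop("degenerate input: all fractional velocities identical")
  Et <- attr(series, "Et_nM")
  It <- series$It_nM
  fv <- series$fv

  # crude start: Ki' from the point nearest half-inhibition, via the exact
  # inversion vs/vo = f  =>  Ki' = f*(It - Et*(1-f)) / (1-f)
  f_mid <- fv[which.min(abs(fv - 0.5))]
  f_mid <- min(max(f_mid, 0.05), 0.95)
  i_mid <- It[which.min(abs(fv - 0.5))]
  ki0 <- max(f_mid * (i_mid - Et * (1 - f_mid)) / (1 - f_mid), Et * 1e-6)

  dat <- data.frame(It = It, fv = fv)
  if (vo_mode == "fixed") {
    fit <- minpack.lm::nlsLM(
      fv ~ morrison_velocity(exp(lki), It, Et, vo = 1),
      data = dat, start = list(lki = log(ki0)),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15))
    vo_hat <- 1
  } else {
    fit <- minpack.lm::nlsLM(
      fv ~ morrison_velocity(exp(lki), It, Et, vo = vo),
      data = dat, start = list(lki = log(ki0), vo = max(fv)),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15))
    vo_hat <- unname(stats::coef(fit)["vo"])
  }
  lki <- unname(stats::coef(fit)["lki"])
  ki_nM <- exp(lki)
  se_lki <- tryCatch(sqrt(diag(stats::vcov(fit)))[["lki"]],
                     error = function(e) NA_real_)
  structure(list(
    Ki_prime_pM = ki_nM * 1e3,
    Ki_prime_se_pM = ki_nM * se_lki * 1e3,  # delta method on log scale
    vo = vo_hat,
    rss = sum(stats::resid(fit)^2),
    Et_nM = Et,
    S_uM = attr(series, "S_uM"),
    tight_binding = ki_nM < Et / 10
  ), class = "tight_binding_fit")
}

#' True Ki and mechanism call from the substrate dependence of Ki'
#'
#' For a competitive inhibitor the apparent constant rises linearly with
#' substrate, Ki'(S) = Ki (1 + S/Km). A (optionally inverse-variance
#' weighted) linear regression of Ki' on S therefore yields the true Ki as
#' the intercept and Km = intercept/slope as a derived diagnostic. The call
#' is `competitive_consistent` when the linearity r-squared reaches
#' `r2_threshold` and the slope is positive; otherwise `nonlinear`.
#'
#' @param S_uM substrate concentrations, uM (>= 3 distinct values)
#' @param Ki_prime_pM apparent inhibition constants, pM
#' @param se_pM optional standard errors of Ki'; when supplied the regression
#'   is weighted by 1/se^2
#' @param r2_threshold linearity threshold for the competitive call
#' @return list of class `competitive_ki_fit`: `Ki_pM`, `Ki_se_pM`,
#'   `slope_pM_per_uM`, `Km_uM`, `linearity_r2`, `mode_call`
#' @export
ki_from_substrate_series <- function(S_uM, Ki_prime_pM, se_pM = NULL,
                                     r2_threshold = 0.9) {
  if (length(unique(S_uM)) < 3L) stop("at least 3 substrate levels required")
  stopifnot(length(S_uM) == length(Ki_prime_pM))
  w <- if (is.null(se_pM)) rep(1, length(S_uM)) else 1 / se_pM^2
  fit <- stats::lm(Ki_prime_pM ~ S_uM, weights = w)
  cf <- stats::coef(fit)
  intercept <- unname(cf[1]); slope <- unname(cf[2])
  if (intercept <= 0) stop("non-positive fitted intercept: no Ki estimate")
  tss <- sum(w * (Ki_prime_pM - stats::weighted.mean(Ki_prime_pM, w))^2)
  r2 <- if (tss == 0) 0 else 1 - sum(w * stats::resid(fit)^2) / tss
  competitive <- is.finite(r2) && r2 >= r2_threshold && slope > 0
  # intercept SE from the normal equations (avoids summary() warnings on
  # residual-free fits, where the SE is legitimately zero)
  xtx_inv <- chol2inv(qr.R(fit$qr))
  sigma2 <- sum(w * stats::resid(fit)^2) / fit$df.residual
  structure(list(
    Ki_pM = intercept,
    Ki_se_pM = sqrt(sigma2 * xtx_inv[1, 1]),
    slope_pM_per_uM = slope,
    Km_uM = if (slope > 0) intercept / slope else NA_real_,
    linearity_r2 = r2,
    mode_call = if (competitive) "competitive_consistent" else "nonlinear"
  ), class = "competitive_ki_fit")
}

#' Logistic (4-parameter) IC50 fit
#'
#' Fits percentage inhibition against log10 concentration with the logistic
#' sigmoid \eqn{y = A_2 + (A_1 - A_2)/(1 + 10^{H (x - x_0)})}, where
#' \eqn{x = \log_{10}} concentration and \eqn{x_0} the inflection, so that
#' IC50 = 10^x0 and y(x0) = (A1 + A2)/2. Asymptotes are unconstrained by
#' default; `constrain = TRUE` pins A1 = 0, A2 = 100 (inhibition is a
#' bounded percentage).
#'
#' @param conc concentrations (any single unit; IC50 is returned in it)
#' @param pct_inhibition responses, percent inhibition
#' @param constrain fix asymptotes to 0/100
#' @return list of class `logistic_fit`: `A1`, `A2`, `x0`, `H`, `IC50`,
#'   `IC50_se`, `rss`, `unit` fields
#' @export
fit_logistic_ic50 <- function(conc, pct_inhibition, constrain = FALSE) {
  stopifnot(length(conc) == length(pct_inhibition), all(conc > 0))
  if (length(unique(conc)) < 4L)
    stop("at least 4 dose levels required")
  if (stats::var(pct_inhibition) == 0) stop("responses are constant")
  x <- log10(conc)
  y <- pct_inhibition
  x0_start <- x[which.min(abs(y - (min(y) + max(y)) / 2))]
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                     ptol = 1e-15)
  logistic4 <- function(p) p[2] + (p[1] - p[2]) / (1 + 10^(p[4] * (x - p[3])))
  if (constrain) {
    resid_fn <- function(p) y - logistic4(c(0, 100, p))
    fit <- minpack.lm::nls.lm(par = c(x0 = x0_start, H = 1), fn = resid_fn,
                              control = ctrl)
    A1 <- 0; A2 <- 100
    x0 <- fit$par[["x0"]]; H <- fit$par[["H"]]
    i_x0 <- 1L
  } else {
    resid_fn <- function(p) y - logistic4(p)
    fit <- minpack.lm::nls.lm(par = c(A1 = min(y), A2 = max(y),
                                      x0 = x0_start, H = 1),
                              fn = resid_fn, control = ctrl)
    A1 <- fit$par[["A1"]]; A2 <- fit$par[["A2"]]
    x0 <- fit$par[["x0"]]; H <- fit$par[["H"]]
    if (isTRUE(all.equal(A1, A2))) stop("degenerate fit: A1 == A2")
    i_x0 <- 3L
  }
  rss <- sum(fit$fvec^2)
  dof <- max(length(y) - length(fit$par), 1)
  se_x0 <- tryCatch(sqrt((rss / dof) * solve(fit$hessian)[i_x0, i_x0]),
                    error = function(e) NA_real_)
  structure(list(A1 = A1, A2 = A2, x0 = x0, H = H,
                 IC50 = 10^x0, IC50_se = 10^x0 * log(10) * se_x0,
                 rss = rss),
            class = "logistic_fit")
}

#' Ki for a non-competitive inhibitor
#'
#' For purely non-competitive inhibition the inhibition constant equals the
#' IC50; this relabels a logistic fit accordingly.
#'
#' @param fit a [fit_logistic_ic50()] result
#' @return list of class `noncompetitive_ki`: `Ki` (same unit as the fitted
#'   concentrations), `Ki_se`, `mode = "noncompetitive"`
#' @export
noncompetitive_ki <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  structure(list(Ki = fit$IC50, Ki_se = fit$IC50_se,
                 mode = "noncompetitive"),
            class = "noncompetitive_ki")
}

#' Percent inhibition from paired velocities
#'
#' 100 (1 - v_inhibited / v_control). Negative values denote activation of
#' the amidolytic activity (observed for some cleavage products).
#'
#' @param v_inhibited velocity with inhibitor, AU/min
#' @param v_control uninhibited velocity, AU/min (> 0)
#' @return percent inhibition
#' @export
percent_inhibition <- function(v_inhibited, v_control) {
  if (any(v_control <= 0)) stop("control velocity must be > 0")
  100 * (1 - v_inhibited / v_control)
}

#' Lower bound on protease selectivity from an inhibition panel
#'
#' Characterises the target protease by the lowest tested concentration at
#' which inhibition reaches `threshold_pct`, and each off-target by the
#' highest tested concentration at which its inhibition stays below the
#' threshold (provided it is not inhibited at any lower concentration). The
#' reported fold is the most conservative across off-targets:
#' min(off-target bounding conc) / min(active target conc), a lower bound on
#' the true selectivity. A fold below 1 is flagged non-selective.
#'
#' @param panel data frame with columns `protease_id`, `inhibitor_conc_M`,
#'   `pct_inhibition`
#' @param target protease_id of the intended target
#' @param threshold_pct inhibition threshold (percent, default 20)
#' @return list of class `selectivity_result`: `fold`, `target_conc_M`,
#'   `offtarget_conc_M`, `limiting_offtarget`, `selective`
#' @export
selectivity_fold <- function(panel, target, threshold_pct = 20) {
  stopifnot(is.data.frame(panel),
            all(c("protease_id", "inhibitor_conc_M", "pct_inhibition") %in%
                  names(panel)))
  tgt <- panel[panel$protease_id == target, , drop = FALSE]
  off <- panel[panel$protease_id != target, , drop = FALSE]
  if (nrow(tgt) == 0L) stop("target protease not present in panel")
  if (nrow(off) == 0L) stop("no off-target rows in panel")
  active <- tgt$pct_inhibition >= threshold_pct
  if (!any(active)) stop("target never reaches the inhibition threshold")
  target_conc <- min(tgt$inhibitor_conc_M[active])

  bound_one <- function(d) {
    d <- d[order(d$inhibitor_conc_M), , drop = FALSE]
    act <- d$pct_inhibition >= threshold_pct
    if (!any(act)) return(max(d$inhibitor_conc_M))
    below <- d$inhibitor_conc_M < min(d$inhibitor_conc_M[act])
    if (!any(below)) return(NA_real_)   # inhibited at the lowest tested conc
    max(d$inhibitor_conc_M[below])
  }
  bounds <- vapply(split(off, off$protease_id), bound_one, numeric(1))
  if (all(is.na(bounds))) stop("no qualifying off-target rows")
  limiting <- names(bounds)[which.min(bounds)]
  off_conc <- min(bounds, na.rm = TRUE)
  if (any(is.na(bounds))) {  # some off-target active below its lowest conc
    limiting <- names(bounds)[is.na(bounds)][1]
    off_conc <- 0
  }
  fold <- off_conc / target_conc
  structure(list(fold = fold, target_conc_M = target_conc,
                 offtarget_conc_M = off_conc,
                 limiting_offtarget = limiting,
                 selective = fold >= 1),
            class = "selectivity_result")
}

#' Fold-potency ratio between two inhibition constants
#'
#' @param ki_a,ki_b inhibition constants, same unit, both > 0
#' @param rounding "none" or "nearest_integer"
#' @return ki_a / ki_b (a fold-improvement of b over a when > 1)
#' @export
ki_fold_ratio <- function(ki_a, ki_b, rounding = c("none", "nearest_integer")) {
  rounding <- match.arg(rounding)
  if (any(c(ki_a, ki_b) <= 0) || any(!is.finite(c(ki_a, ki_b))))
    stop("inhibition constants must be positive and finite")
  fold <- ki_a / ki_b
  if (rounding == "nearest_integer") round(fold) else fold
}

#' Bundled peptide inhibition-constant table
#'
#' Sequences and thrombin inhibition constants (pM, mean +/- SD) for
#' bivalirudin, variegin, avathrin, the DAA34688.1 repeat peptides,
#' ultravariegin and its variants, as transcribed from the source study.
#' BV001 (the bivalirudin cleavage product) carries `NA`: it does not
#' inhibit thrombin and instead activates it at micromolar concentrations.
#'
#' @return data frame with columns `peptide_id`, `sequence`, `Ki_pM`,
#'   `Ki_SE_pM`
#' @export
peptide_ki_table <- function() {
  path <- system.file("extdata", "table1_ki.csv", package = "dtikin",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
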