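#' Saline baselines for the rodent models
#'
#' Mean response times of saline-treated animals: carotid-artery occlusion
#' 8.82 min, tail-incision bleeding 4.25 min. Used as the default fixed
#' baseline of the RT50 dose-response when no saline group is supplied.
#'
#' @format named numeric vector (minutes)
#' @export
saline_baselines <- c(occlusion = 8.82, tail_bleed = 4.25)

hill_response_time <- function(dose, baseline, cap, rt50, hill) {
  ifelse(dose <= 0, baseline,
         baseline + (cap - baseline) / (1 + (rt50 / dose)^hill))
}

#' Fit a cap-censored RT50 dose-response
#'
#' Models the latent response time (occlusion or bleeding time) as a Hill
#' curve rising from a fixed baseline to the observation cap,
#' RT(d) = baseline + (cap - baseline) / (1 + (rt50/d)^hill), with
#' multiplicative log-normal residuals. Observations recorded at the cap
#' (censored) contribute log-normal survival terms to the likelihood rather
#' than being discarded or treated as exact. RT50 - the dose at which the
#' latent curve reaches the midpoint (baseline + cap)/2 - equals the `rt50`
#' parameter by construction.
#'
#' Uncensored data are first fitted by least squares on the log scale; when
#' censored records are present the fit is refined by full censored maximum
#' likelihood.
#'
#' @param records data frame with columns `dose` (> 0 for treated animals;
#'   dose 0 rows, if any, are the saline group), `response_time_min`,
#'   `censored` (logical)
#' @param cap observation cap in minutes (e.g. 60 for the rat models)
#' @param baseline fixed baseline response time (min); default: mean of the
#'   dose-0 records
#' @param dose_unit unit tag carried into the fit (e.g. "mg/kg", "U/kg")
#' @return list of class `rt50_fit`: `rt50_dose`, `hill`, `sigma_log`,
#'   `baseline`, `cap`, `dose_unit`, `n`, `n_censored`, `converged`
#' @export
fit_rt50 <- function(records, cap, baseline = NULL, dose_unit = "mg/kg") {
  stopifnot(is.data.frame(records),
            all(c("dose", "response_time_min", "censored") %in%
                  names(records)))
  if (cap <= 0) stop("cap must be positive")
  if (is.null(baseline)) {
    sal <- records$dose == 0
    if (!any(sal)) stop("no saline (dose 0) group and no baseline supplied")
    baseline <- mean(records$response_time_min[sal])
  }
  if (baseline >= cap) stop("baseline must lie below the cap")
  d <- records[records$dose > 0, , drop = FALSE]
  if (length(unique(d$dose)) < 3L) stop("at least 3 dose levels required")
  if (all(d$censored)) stop("no information below cap: all records censored")
  y <- pmin(d$response_time_min, cap)
  if (all(abs(y - baseline) / baseline < 0.02))
    stop("all responses at baseline: no dose effect to fit")

  unc <- !d$censored
  # stage 1: log-scale least squares on uncensored records
  obj_ls <- function(p) {
    mu <- hill_response_time(d$dose[unc], baseline, cap, exp(p[1]), exp(p[2]))
    sum((log(y[unc]) - log(mu))^2)
  }
  mid <- (baseline + cap) / 2
  d_start <- d$dose[unc][which.min(abs(y[unc] - mid))]
  p0 <- c(log(d_start), log(1))
  ls <- stats::optim(p0, obj_ls, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-14))
  # polish with BFGS for tight noiseless recovery
  ls <- stats::optim(ls$par, obj_ls, method = "BFGS",
                     control = list(maxit = 1000, reltol = 1e-14))
  rt50 <- exp(ls$par[1]); hill <- exp(ls$par[2])
  sigma <- sqrt(max(ls$value / max(sum(unc) - 2, 1), 1e-12))
  converged <- ls$convergence == 0

  if (any(d$censored)) {
    nll <- function(p) {
      mu <- hill_response_time(d$dose, baseline, cap, exp(p[1]), exp(p[2]))
      s <- exp(p[3])
      z <- (log(y) - log(mu)) / s
      ll <- numeric(nrow(d))
      ll[unc] <- stats::dnorm(z[unc], log = TRUE) - log(s) - log(y[unc])
      cen <- d$censored
      ll[cen] <- stats::pnorm((log(cap) - log(mu[cen])) / s,
                              lower.tail = FALSE, log.p = TRUE)
      -sum(ll)
    }
    ml <- stats::optim(c(log(rt50), log(hill), log(max(sigma, 1e-3))), nll,
                       method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-12))
    rt50 <- exp(ml$par[1]); hill <- exp(ml$par[2]); sigma <- exp(ml$par[3])
    converged <- ml$convergence == 0
  }
  structure(list(rt50_dose = rt50, hill = hill, sigma_log = sigma,
                 baseline = baseline, cap = cap, dose_unit = dose_unit,
                 n = nrow(d), n_censored = sum(d$censored),
                 converged = converged),
            class = "rt50_fit")
}

#' Therapeutic index from bleeding and occlusion RT50 fits
#'
#' TI = RT50(bleeding) / RT50(occlusion): the fold separation between the
#' dose that halves the bleeding response and the dose that halves the
#' antithrombotic (occlusion) response. Larger is safer.
#'
#' @param bleed,occl [fit_rt50()] results in the same dose unit
#' @return list of class `therapeutic_index_result`: `rt50_bleeding`,
#'   `rt50_occlusion`, `ti`, `dose_unit`
#' @export
therapeutic_index <- function(bleed, occl) {
  stopifnot(inherits(bleed, "rt50_fit"), inherits(occl, "rt50_fit"))
  if (!identical(bleed$dose_unit, occl$dose_unit))
    stop("dose-unit mismatch between bleeding and occlusion fits")
  structure(list(rt50_bleeding = bleed$rt50_dose,
                 rt50_occlusion = occl$rt50_dose,
                 ti = bleed$rt50_dose / occl$rt50_dose,
                 dose_unit = bleed$dose_unit),
            class = "therapeutic_index_result")
}

#' Saphenous-vein bleeding metrics
#'
#' Average time per bleeding event over the observation window: window /
#' number of clots. Zero clots within the window means haemostasis never
#' occurred; the result is censored with the bleeding time reported at the
#' window length (a lower bound).
#'
#' @param n_clots number of haemostatic events in the window
#' @param window_min observation window, minutes (default 30)
#' @return list of class `saphenous_result`: `n_clots`, `avg_bleed_time_min`,
#'   `censored`
#' @export
saphenous_metrics <- function(n_clots, window_min = 30) {
  if (window_min <= 0) stop("window must be positive")
  if (n_clots < 0 || n_clots != round(n_clots)) stop("n_clots must be a count")
  if (n_clots == 0) {
    return(structure(list(n_clots = 0L, avg_bleed_time_min = window_min,
                          censored = TRUE),
                     class = "saphenous_result"))
  }
  structure(list(n_clots = as.integer(n_clots),
                 avg_bleed_time_min = window_min / n_clots,
                 censored = FALSE),
            class = "saphenous_result")
}

#' Pearson correlation between paired model endpoints
#'
#' @param x,y paired group means (n >= 3)
#' @return list: `r`, `p` (two-tailed, t-transform), `n`
#' @export
cross_model_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("at least 3 paired values required")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in one of the vectors")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Two-sample t test
#'
#' @param a,b numeric groups (each n >= 2)
#' @param variant "student" (pooled variance) or "welch"
#' @return list: `t`, `p` (two-tailed), `df`
#' @export
two_sample_ttest <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("zero pooled variance")
  tt <- stats::t.test(a, b, var.equal = (variant == "student"),
                      alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}
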