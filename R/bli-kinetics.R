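bli_association <- function(t, kon, koff, Rmax, conc_M) {
  KD <- koff / kon
  req <- Rmax * conc_M / (conc_M + KD)
  kobs <- kon * conc_M + koff
  req * (1 - exp(-kobs * t))
}

#' Simulate a 1:1 biolayer-interferometry sensorgram
#'
#' Closed-form Langmuir 1:1 binding: the association phase follows
#' R(t) = Rmax C/(C + KD) (1 - e^{-(kon C + koff) t}) and the dissociation
#' phase decays mono-exponentially, R(t) = R_end e^{-koff t}, from the
#' association end-point. KD = koff/kon.
#'
#' @param kon association rate constant, 1/(M s)
#' @param koff dissociation rate constant, 1/s
#' @param Rmax saturating response, nm
#' @param conc_nM analyte concentration, nM (0 allowed: reference trace)
#' @param t_assoc,t_dissoc phase durations, s
#' @param dt sampling interval, s
#' @return data frame of class `sensorgram`: `time_s`, `response_nm`,
#'   `phase` ("association"/"dissociation"), `conc_nM`; attribute `truth`
#'   records the generating parameters
#' @export
simulate_1to1 <- function(kon, koff, Rmax, conc_nM, t_assoc = 2400,
                          t_dissoc = 3600, dt = 1) {
  if (kon <= 0 || koff <= 0 || Rmax <= 0)
    stop("kon, koff and Rmax must be positive")
  if (conc_nM < 0) stop("analyte concentration must be >= 0")
  if (t_assoc <= 0 || t_dissoc <= 0 || dt <= 0)
    stop("phase durations and dt must be positive")
  C <- conc_nM * 1e-9
  ta <- seq(0, t_assoc, by = dt)
  td <- seq(dt, t_dissoc, by = dt)
  ra <- bli_association(ta, kon, koff, Rmax, C)
  r_end <- ra[length(ra)]
  rd <- r_end * exp(-koff * td)
  out <- data.frame(
    time_s = c(ta, t_assoc + td),
    response_nm = c(ra, rd),
    phase = rep(c("association", "dissociation"), c(length(ta), length(td))),
    conc_nM = conc_nM
  )
  structure(out,
            truth = list(kon = kon, koff = koff, Rmax = Rmax,
                         KD_nM = koff / kon * 1e9),
            class = c("sensorgram", "data.frame"))
}

#' Global 1:1 kinetic fit across a dilution series
#'
#' Nonlinear least squares of the 1:1 closed forms to association and
#' dissociation data. In the default global mode a single (kon, koff, Rmax)
#' triplet is shared across all concentrations, matching vendor practice for
#' a dilution series; `per_curve` fits each trace separately (the observed
#' rate kobs = kon C + koff and koff are reported per concentration, a
#' diagnostic for mass-transport or heterogeneity artefacts). Parameters are
#' fitted on the log scale to enforce positivity.
#'
#' @param sensorgrams one `sensorgram` or a list of them (one per analyte
#'   concentration)
#' @param mode "global" or "per_curve"
#' @return for global mode, list of class `one_to_one_fit`: `kon` (1/(M s)),
#'   `koff` (1/s), `KD_kinetic_nM` (= koff/kon, exactly), `Rmax_nm`, `rss`,
#'   `ill_conditioned` (TRUE when all concentrations are far from KD);
#'   for per_curve mode a data frame with `conc_nM`, `kobs`, `koff`, `kon`
#' @export
fit_1to1 <- function(sensorgrams, mode = c("global", "per_curve")) {
  mode <- match.arg(mode)
  if (inherits(sensorgrams, "sensorgram")) sensorgrams <- list(sensorgrams)
  stopifnot(all(vapply(sensorgrams, inherits, TRUE, "sensorgram")))
  concs <- vapply(sensorgrams, function(s) s$conc_nM[1], numeric(1))

  if (mode == "per_curve") {
    rows <- lapply(sensorgrams, function(s) {
      C <- s$conc_nM[1] * 1e-9
      a <- s[s$phase == "association", ]
      d <- s[s$phase == "dissociation", ]
      td <- d$time_s - max(a$time_s)
      koff_fit <- minpack.lm::nlsLM(
        response_nm ~ r0 * exp(-exp(lkoff) * td),
        data = cbind(d, td = td),
        start = list(r0 = max(d$response_nm), lkoff = log(1e-3)))
      koff_hat <- exp(unname(stats::coef(koff_fit)["lkoff"]))
      assoc_fit <- minpack.lm::nlsLM(
        response_nm ~ req * (1 - exp(-exp(lkobs) * time_s)),
        data = a,
        start = list(req = max(a$response_nm), lkobs = log(1e-3)))
      kobs_hat <- exp(unname(stats::coef(assoc_fit)["lkobs"]))
      data.frame(conc_nM = s$conc_nM[1], kobs = kobs_hat, koff = koff_hat,
                 kon = if (C > 0) (kobs_hat - koff_hat) / C else NA_real_)
    })
    return(do.call(rbind, rows))
  }

  if (length(sensorgrams) < 3L)
    stop("global fit requires at least 3 concentrations")
  all_df <- do.call(rbind, lapply(sensorgrams, function(s) {
    s$t_assoc_end <- max(s$time_s[s$phase == "association"])
    as.data.frame(s)
  }))
  model_resp <- function(kon, koff, Rmax, df) {
    C <- df$conc_nM * 1e-9
    assoc <- df$phase == "association"
    r <- numeric(nrow(df))
    r[assoc] <- bli_association(df$time_s[assoc], kon, koff, Rmax, C[assoc])
    dis <- !assoc
    r_end <- bli_association(df$t_assoc_end[dis], kon, koff, Rmax, C[dis])
    r[dis] <- r_end * exp(-koff * (df$time_s[dis] - df$t_assoc_end[dis]))
    r
  }
  resid_fn <- function(p) {
    all_df$response_nm - model_resp(exp(p[1]), exp(p[2]), exp(p[3]), all_df)
  }
  rmax0 <- max(all_df$response_nm) * 1.1
  start <- c(log(1e5), log(1e-3), log(rmax0))
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 1000, ftol = 1e-15, ptol = 1e-15))
  kon <- exp(fit$par[1]); koff <- exp(fit$par[2]); rmax <- exp(fit$par[3])
  KD_nM <- koff / kon * 1e9
  pos <- concs[concs > 0]
  ill <- length(pos) > 0 &&
    (all(pos < KD_nM / 100) || all(pos > KD_nM * 100))
  structure(list(kon = kon, koff = koff, KD_kinetic_nM = KD_nM,
                 Rmax_nm = rmax, rss = sum(fit$fvec^2),
                 ill_conditioned = ill),
            class = "one_to_one_fit")
}

#' Equilibrium response of an association phase
#'
#' Fits the association phase to a mono-exponential approach to plateau,
#' R(t) = Req (1 - e^{-kobs t}), and reports the fitted plateau Req - not
#' the last sample, which underestimates Req whenever the phase ends before
#' equilibrium. Traces far from equilibrium (plateau standard error above
#' 50% of the estimate, or fit failure) are flagged unreliable.
#'
#' @param sensorgram a `sensorgram` (association phase required)
#' @return list: `Req_nm`, `Req_se`, `kobs`, `reliable`
#' @export
extract_req <- function(sensorgram) {
  stopifnot(inherits(sensorgram, "sensorgram"))
  a <- sensorgram[sensorgram$phase == "association", ]
  if (nrow(a) < 5L) stop("association phase absent or too short")
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nlsLM(response_nm ~ req * (1 - exp(-exp(lkobs) * time_s)),
                        data = a,
                        start = list(req = max(a$response_nm) * 1.05,
                                     lkobs = log(2 / max(a$time_s))))),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(Req_nm = NA_real_, Req_se = NA_real_, kobs = NA_real_,
                reliable = FALSE))
  }
  cf <- stats::coef(fit)
  req <- unname(cf["req"])
  kobs <- exp(unname(cf["lkobs"]))
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["req"]],
                 error = function(e) NA_real_)
  reliable <- is.finite(se) && req > 0 && se / req <= 0.5 &&
    kobs * max(a$time_s) >= 1
  list(Req_nm = req, Req_se = se, kobs = kobs, reliable = reliable)
}

#' Steady-state affinity from the binding isotherm
#'
#' Least-squares fit of the Langmuir isotherm Req = Rmax C / (KD + C) to
#' equilibrium responses across a concentration series, yielding the
#' equilibrium dissociation constant KD independent of the kinetic route.
#'
#' @param conc_nM analyte concentrations, nM (>= 3 levels)
#' @param Req_nm equilibrium responses, nm
#' @return list of class `steady_state_fit`: `KD_eq_nM`, `Rmax_nm`,
#'   `saturated` (TRUE when the fitted KD falls far below the tested range,
#'   i.e. the design cannot resolve it)
#' @export
fit_steady_state <- function(conc_nM, Req_nm) {
  stopifnot(length(conc_nM) == length(Req_nm))
  if (length(unique(conc_nM)) < 3L) stop("at least 3 concentrations required")
  if (any(conc_nM <= 0)) stop("concentrations must be positive")
  resid_fn <- function(p)
    Req_nm - p[1] * conc_nM / (exp(p[2]) + conc_nM)
  fit <- minpack.lm::nls.lm(par = c(rmax = max(Req_nm) * 1.1,
                                    lkd = log(stats::median(conc_nM))),
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  kd <- exp(fit$par[["lkd"]])
  rmax <- fit$par[["rmax"]]
  structure(list(KD_eq_nM = kd, Rmax_nm = rmax,
                 saturated = kd < min(conc_nM) / 100),
            class = "steady_state_fit")
}
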