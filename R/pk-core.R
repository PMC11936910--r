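#' Individual clearance under the covariate power model
#'
#' Evaluates
#' \deqn{CL = \theta_{CL} (CrCL/CrCL_{med})^{\theta_{CrCL}}
#'            (PLT/PLT_{med})^{\theta_{PLT}} e^{\eta},}
#' the final covariate model for polymyxin B clearance. At the covariate
#' medians and \eqn{\eta = 0} this returns the typical clearance.
#'
#' @param params A [pk_params] object.
#' @param crcl Creatinine clearance (mL/min); vectorised.
#' @param plt Platelet count (1e9/L); vectorised.
#' @param eta_cl Log-scale individual deviation(s), default 0.
#' @return Clearance (L/h), recycled to the common length of the inputs.
#' @examples
#' p <- pmb_reference_params()
#' individual_clearance(p, crcl = 75.99, plt = 163.5)   # typical value
#' individual_clearance(p, crcl = 30, plt = 85)         # renal impairment
#' @export
individual_clearance <- function(params, crcl, plt, eta_cl = 0) {
  stopifnot(inherits(params, "pk_params"))
  if (any(!is.finite(crcl)) || any(crcl <= 0)) stop("'crcl' must be positive")
  if (any(!is.finite(plt)) || any(plt <= 0)) stop("'plt' must be positive")
  params$theta_cl *
    (crcl / params$crcl_median)^params$exp_crcl *
    (plt / params$plt_median)^params$exp_plt *
    exp(eta_cl)
}

#' Individual pharmacokinetic parameters
#'
#' Builds the individual clearance/volume pair (and the derived elimination
#' rate constant `ke = cl/v`) for given covariates and random effects.
#'
#' @inheritParams individual_clearance
#' @param eta_v Log-scale deviation on volume, default 0.
#' @return A data.frame with columns `cl` (L/h), `v` (L), `ke` (1/h),
#'   `eta_cl`, `eta_v`.
#' @examples
#' individual_pk(pmb_reference_params(), crcl = 75.99, plt = 163.5)
#' @export
individual_pk <- function(params, crcl, plt, eta_cl = 0, eta_v = 0) {
  cl <- individual_clearance(params, crcl, plt, eta_cl)
  v <- params$theta_v * exp(eta_v)
  n <- max(length(cl), length(v))
  data.frame(cl = rep_len(cl, n), v = rep_len(v, n),
             ke = rep_len(cl, n) / rep_len(v, n),
             eta_cl = rep_len(eta_cl, n), eta_v = rep_len(eta_v, n))
}

# single-dose infusion concentration at time `t` after infusion start
# (vectorised over everything; uses expm1 so the bolus limit t_inf -> 0 is
# accurate to machine precision)
conc_single_dose <- function(cl, ke, amt, t_inf, t) {
  te <- pmin(pmax(t, 0), t_inf)
  r0 <- amt / t_inf
  (r0 / cl) * (-expm1(-ke * te)) * exp(-ke * pmax(t - t_inf, 0)) * (t > 0)
}

#' Steady-state concentration within a dosing interval
#'
#' Closed-form one-compartment solution for repeated intermittent infusion at
#' steady state. With infusion rate \eqn{R_0 = dose/t_{inf}} and accumulation
#' term \eqn{1 - e^{-k_e \tau}}, the concentration during the infusion
#' (\eqn{t \le t_{inf}}) is
#' \deqn{C(t) = \frac{R_0}{CL}\left[(1 - e^{-k_e t}) +
#'   \frac{e^{-k_e\tau} (1 - e^{-k_e t_{inf}}) e^{-k_e (t - t_{inf})}}
#'        {1 - e^{-k_e\tau}}\right],}
#' and afterwards the end-of-infusion peak decays mono-exponentially. The two
#' branches are continuous at \eqn{t = t_{inf}}.
#'
#' @param ind Individual parameters: anything with elements `cl` and `v`
#'   (e.g. one row of [individual_pk()]).
#' @param reg A [regimen] (its `n_doses`/`loading_dose` are ignored: steady
#'   state is assumed).
#' @param t Time (h) since the start of an infusion; vectorised, must lie in
#'   `[0, tau)`.
#' @return Concentration (mg/L).
#' @examples
#' ind <- individual_pk(pmb_reference_params(), 75.99, 163.5)
#' reg <- regimen(75, tau = 12, t_inf = 1)
#' conc_ss(ind, reg, t = 1)              # end-of-infusion peak
#' conc_ss(ind, reg, t = 12 - 1e-9)      # trough
#' @export
conc_ss <- function(ind, reg, t) {
  stopifnot(inherits(reg, "regimen"))
  cl <- ind$cl; v <- ind$v
  stopifnot(all(cl > 0), all(v > 0))
  if (any(t < 0 | t >= reg$tau)) stop("'t' must lie in [0, tau)")
  ke <- cl / v
  r0 <- reg$dose / reg$t_inf
  acc <- -expm1(-ke * reg$tau)
  peak <- (r0 / cl) * (-expm1(-ke * reg$t_inf)) / acc
  during <- (r0 / cl) * (-expm1(-ke * pmin(t, reg$t_inf))) +
    peak * exp(-ke * reg$tau) * exp(-ke * (pmin(t, reg$t_inf) - reg$t_inf))
  after <- peak * exp(-ke * (t - reg$t_inf))
  ifelse(t <= reg$t_inf, during, after)
}

#' Concentration from the first dose by superposition
#'
#' Sums the single-infusion solutions of all administrations started before
#' `t` (the loading dose, when present, is the first administration). As the
#' number of prior doses grows this converges to the steady-state profile
#' [conc_ss()].
#'
#' @inheritParams conc_ss
#' @param t Time (h) since the start of the first infusion; vectorised,
#'   `t >= 0`.
#' @return Concentration (mg/L).
#' @examples
#' ind <- individual_pk(pmb_reference_params(), 75.99, 163.5)
#' reg <- regimen(75, tau = 12, t_inf = 1, n_doses = 5, loading_dose = 150)
#' conc_superposition(ind, reg, t = c(1, 12, 49))
#' @export
conc_superposition <- function(ind, reg, t) {
  stopifnot(inherits(reg, "regimen"), all(t >= 0))
  cl <- ind$cl[1]; v <- ind$v[1]
  ke <- cl / v
  amt <- regimen_amounts(reg)
  dose_times <- (seq_along(amt) - 1) * reg$tau
  out <- numeric(length(t))
  for (d in seq_along(amt)) {
    out <- out + conc_single_dose(cl, ke, amt[d], reg$t_inf, t - dose_times[d])
  }
  out
}

#' Model-based steady-state 24-hour AUC
#'
#' For linear kinetics the steady-state area under the concentration-time
#' curve over 24 h is the total daily dose divided by clearance.
#'
#' @param cl Clearance (L/h); vectorised.
#' @param daily_dose Total dose administered per 24 h (mg).
#' @return AUC over 24 h at steady state (mg.h/L).
#' @examples
#' auc_model(2.03, 150)
#' @export
auc_model <- function(cl, daily_dose) {
  if (any(!is.finite(cl)) || any(cl <= 0)) stop("'cl' must be positive")
  stopifnot(all(daily_dose > 0))
  daily_dose / cl
}
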