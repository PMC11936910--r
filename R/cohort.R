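#' Calibrate a log-normal distribution from a median and quartiles
#'
#' Matches a log-normal to a reported median and interquartile range:
#' `meanlog = log(median)` and `sdlog = (log(q3) - log(q1)) / (2 * 0.6745)`,
#' since the quartiles of a normal sit 0.6745 SD from its mean.
#'
#' @param median,q1,q3 Reported median and lower/upper quartiles (> 0).
#' @return A list with `meanlog` and `sdlog`.
#' @examples
#' lognormal_from_quartiles(75.99, 38.46, 130.58)   # CrCL calibration
#' @export
lognormal_from_quartiles <- function(median, q1, q3) {
  stopifnot(median > 0, q1 > 0, q3 > q1)
  list(meanlog = log(median),
       sdlog = (log(q3) - log(q1)) / (2 * stats::qnorm(0.75)))
}

#' Specification of a synthetic polymyxin B cohort
#'
#' Describes the virtual study population used throughout the package:
#' independent log-normal covariate distributions calibrated to the reported
#' median/IQR of the modelled intensive-care population (CrCL median
#' 75.99 mL/min, IQR 38.46-130.58; platelets median 163.5e9/L, IQR
#' 84.5-266.25), a q12h one-hour-infusion regimen with a loading dose (twice
#' the maintenance dose by default), and paired trough/peak sampling in the
#' first interval at or after 48 h of treatment.
#'
#' @param n_subjects Number of virtual patients.
#' @param crcl,plt Lists with `median`, `q1`, `q3` calibrating the log-normal
#'   covariate distributions (set `q1 = q3 = median` for a degenerate,
#'   zero-spread distribution... any `q3 > q1` works).
#' @param age List with `mean`, `sd`, `min`, `max` for a truncated normal age
#'   distribution (years).
#' @param weight List with `median`, `q1`, `q3` (kg), log-normal.
#' @param p_male Proportion of male subjects.
#' @param regimen A [regimen]; its `n_doses` is raised automatically if too
#'   few doses cover the sampling window.
#' @param first_obs_time Start (h) of the sampled dosing interval; default 48,
#'   i.e. sampling after at least 48 h of treatment.
#' @param n_occasions Trough/peak occasions per subject (subsequent occasions
#'   are 24 h apart).
#' @param lloq Lower limit of quantification (mg/L); observations below it are
#'   flagged, not dropped.
#' @param seed Default random seed used by [simulate_tdm()].
#' @return An object of class `cohort_spec`.
#' @examples
#' cohort_spec(n_subjects = 20, seed = 1)
#' @export
cohort_spec <- function(n_subjects = 80,
                        crcl = list(median = 75.99, q1 = 38.46, q3 = 130.58),
                        plt = list(median = 163.5, q1 = 84.5, q3 = 266.25),
                        age = list(mean = 60, sd = 15, min = 18, max = 95),
                        weight = list(median = 63, q1 = 55, q3 = 74),
                        p_male = 0.75,
                        regimen = pmbpk::regimen(75, tau = 12, t_inf = 1,
                                                 n_doses = 5,
                                                 loading_dose = 150),
                        first_obs_time = 48,
                        n_occasions = 1,
                        lloq = 0.2,
                        seed = NULL) {
  stopifnot(n_subjects >= 1, inherits(regimen, "regimen"),
            n_occasions >= 1, p_male >= 0, p_male <= 1, first_obs_time > 0)
  structure(list(n_subjects = as.integer(n_subjects), crcl = crcl, plt = plt,
                 age = age, weight = weight, p_male = p_male,
                 regimen = regimen, first_obs_time = first_obs_time,
                 n_occasions = as.integer(n_occasions), lloq = lloq,
                 seed = seed),
            class = "cohort_spec")
}

# log-normal draw from a median/quartile calibration; degenerate when q1 == q3
rlnorm_cal <- function(n, cal) {
  if (cal$q3 <= cal$q1) return(rep(cal$median, n))
  p <- lognormal_from_quartiles(cal$median, cal$q1, cal$q3)
  stats::rlnorm(n, p$meanlog, p$sdlog)
}

#' Sample subject covariates
#'
#' Draws per-subject covariates from the generative distributions of a
#' [cohort_spec]: independent log-normals for creatinine clearance, platelet
#' count and weight, truncated-normal age, Bernoulli sex.
#'
#' @param spec A [cohort_spec].
#' @param seed Random seed; defaults to `spec$seed`.
#' @return A data.frame with columns `ID`, `CRCL`, `PLT`, `WT`, `AGE`, `SEX`
#'   (1 = male, 0 = female).
#' @examples
#' head(sample_covariates(cohort_spec(n_subjects = 5, seed = 1)))
#' @export
sample_covariates <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_subjects
  age <- stats::rnorm(n, spec$age$mean, spec$age$sd)
  age <- pmin(pmax(age, spec$age$min), spec$age$max)
  data.frame(ID = seq_len(n),
             CRCL = rlnorm_cal(n, spec$crcl),
             PLT = rlnorm_cal(n, spec$plt),
             WT = rlnorm_cal(n, spec$weight),
             AGE = age,
             SEX = as.integer(stats::runif(n) < spec$p_male))
}

#' Simulate a trough/peak therapeutic drug monitoring cohort
#'
#' Generates a full synthetic study: covariates via [sample_covariates()],
#' per-subject random effects \eqn{\eta_{CL} \sim N(0, \omega_{CL}^2)} (and
#' \eqn{\eta_V} when `omega_v > 0`), concentrations by dose superposition
#' ([conc_superposition()]) at the trough (immediately pre-dose) and peak
#' (end of infusion) of the first dosing interval at or after
#' `spec$first_obs_time`, and observed values under the combined residual
#' model \eqn{y = f(1 + \varepsilon_1) + \varepsilon_2}. Negative observed
#' values are truncated at zero and flagged; values below the LLOQ are
#' flagged but kept.
#'
#' @param spec A [cohort_spec].
#' @param params A [pk_params] providing the generative fixed effects, IIV
#'   and residual error.
#' @param seed Random seed; defaults to `spec$seed`. Identical seeds give
#'   bit-identical cohorts.
#' @return An object of class `pmb_cohort`: a list with
#'   \describe{
#'     \item{subjects}{per-subject table (covariates, `eta_cl`, `eta_v`,
#'       individual `cl`, `v`)}
#'     \item{obs}{observation table (`ID`, `OCC`, `TIME`, `TYPE`, `TRUE_C`,
#'       `DV`, `FLAG`)}
#'     \item{data}{analysis-ready longitudinal table with columns `ID`,
#'       `TIME`, `AMT`, `RATE`, `DV`, `EVID`, `MDV`, `CRCL`, `PLT`, `WT`,
#'       `AGE`, `SEX`, `OCC` (dose rows `EVID = 1`, observations `EVID = 0`)}
#'     \item{spec, params, seed}{provenance}
#'   }
#' @examples
#' co <- simulate_tdm(cohort_spec(n_subjects = 4, seed = 7),
#'                    pmb_reference_params())
#' head(co$data)
#' @export
simulate_tdm <- function(spec, params, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(params, "pk_params"))
  if (!is.null(seed)) set.seed(seed)
  subj <- sample_covariates(spec, seed = NULL)  # uses the stream seeded above
  n <- nrow(subj)
  subj$eta_cl <- if (params$omega_cl > 0) stats::rnorm(n, 0, params$omega_cl) else rep(0, n)
  subj$eta_v <- if (params$omega_v > 0) stats::rnorm(n, 0, params$omega_v) else rep(0, n)
  subj$cl <- individual_clearance(params, subj$CRCL, subj$PLT, subj$eta_cl)
  subj$v <- params$theta_v * exp(subj$eta_v)

  reg <- spec$regimen
  # first sampled interval starts at the first dose time >= first_obs_time
  k0 <- ceiling(spec$first_obs_time / reg$tau)
  trough_times <- k0 * reg$tau + (seq_len(spec$n_occasions) - 1) * 24
  need <- ceiling((max(trough_times) + reg$t_inf) / reg$tau) + 1
  if (reg$n_doses < need) {
    reg <- regimen(reg$dose, reg$tau, reg$t_inf, n_doses = need,
                   loading_dose = reg$loading_dose)
  }

  obs <- do.call(rbind, lapply(seq_len(spec$n_occasions), function(occ) {
    tt <- trough_times[occ]
    data.frame(ID = rep(subj$ID, 2), OCC = occ,
               TIME = rep(c(tt, tt + reg$t_inf), each = n),
               TYPE = rep(c("trough", "peak"), each = n))
  }))
  obs <- obs[order(obs$ID, obs$TIME, obs$TYPE == "peak"), ]
  cl_o <- subj$cl[obs$ID]; ke_o <- cl_o / subj$v[obs$ID]
  amts <- regimen_amounts(reg)
  true_c <- numeric(nrow(obs))
  for (d in seq_along(amts)) {
    true_c <- true_c +
      conc_single_dose(cl_o, ke_o, amts[d], reg$t_inf,
                       obs$TIME - (d - 1) * reg$tau)
  }
  obs$TRUE_C <- true_c
  eps1 <- if (params$sigma_prop > 0) stats::rnorm(nrow(obs), 0, params$sigma_prop) else 0
  eps2 <- if (params$sigma_add > 0) stats::rnorm(nrow(obs), 0, params$sigma_add) else 0
  dv <- true_c * (1 + eps1) + eps2
  obs$FLAG <- ifelse(dv < 0, "truncated",
                     ifelse(dv < spec$lloq, "below LLOQ", "ok"))
  obs$DV <- pmax(dv, 0)

  amt <- regimen_amounts(reg)
  doses <- data.frame(ID = rep(subj$ID, each = reg$n_doses),
                      TIME = rep((seq_len(reg$n_doses) - 1) * reg$tau, n),
                      AMT = rep(amt, n))
  doses$RATE <- doses$AMT / reg$t_inf
  dose_rows <- data.frame(ID = doses$ID, TIME = doses$TIME, AMT = doses$AMT,
                          RATE = doses$RATE, DV = NA_real_, EVID = 1L,
                          MDV = 1L, OCC = 0L)
  obs_rows <- data.frame(ID = obs$ID, TIME = obs$TIME, AMT = 0, RATE = 0,
                         DV = obs$DV, EVID = 0L, MDV = 0L, OCC = obs$OCC)
  dat <- rbind(dose_rows, obs_rows)
  # pre-dose troughs sort before the simultaneous dose record
  dat <- dat[order(dat$ID, dat$TIME, dat$EVID), ]
  dat <- merge(dat, subj[, c("ID", "CRCL", "PLT", "WT", "AGE", "SEX")],
               by = "ID", sort = FALSE)
  dat <- dat[, c("ID", "TIME", "AMT", "RATE", "DV", "EVID", "MDV",
                 "CRCL", "PLT", "WT", "AGE", "SEX", "OCC")]
  rownames(dat) <- rownames(obs) <- NULL
  structure(list(subjects = subj, obs = obs, data = dat,
                 spec = spec, params = params, seed = seed,
                 regimen = reg),
            class = "pmb_cohort")
}

#' @export
print.pmb_cohort <- function(x, ...) {
  cat(sprintf("Synthetic TDM cohort: %d subjects, %d observations (%d flagged)\n",
              nrow(x$subjects), nrow(x$obs), sum(x$obs$FLAG != "ok")))
  print(x$regimen)
  invisible(x)
}

#' Cockcroft-Gault creatinine clearance
#'
#' \deqn{CrCL = \frac{(140 - age)\, weight}{72\, S_{cr}[mg/dL]}
#'       \times (0.85\ \mathrm{if\ female}),}
#' with serum creatinine supplied in umol/L (divided by 88.4 to convert to
#' mg/dL).
#'
#' @param age Age (years), `< 140`.
#' @param weight Total body weight (kg).
#' @param scr Serum creatinine (umol/L).
#' @param sex `"male"` or `"female"` (vectorised, partial-match tolerant via
#'   exact values only).
#' @return Creatinine clearance (mL/min).
#' @examples
#' cockcroft_gault(40, 72, 88.4, "male")    # 100 by construction
#' cockcroft_gault(40, 72, 88.4, "female")  # 85
#' @export
cockcroft_gault <- function(age, weight, scr, sex) {
  stopifnot(all(age > 0), all(weight > 0), all(scr > 0))
  if (any(age >= 140)) stop("'age' must be below 140 years")
  sex <- match.arg(as.character(sex), c("male", "female"), several.ok = TRUE)
  fac <- ifelse(sex == "female", 0.85, 1)
  ((140 - age) * weight) / (72 * (scr / 88.4)) * fac
}

#' Total polymyxin B concentration from its two major components
#'
#' Combines the separately assayed B1 and B2 component concentrations on a
#' molar basis: `(c1/mw1 + c2/mw2) * mw_total`. Molecular weights are
#' configuration values; the defaults are the literature free-base masses of
#' polymyxin B1 (1203.5 g/mol) and B2 (1189.5 g/mol), with the total reported
#' on the B1 mass scale. They are documented defaults, not assay constants.
#'
#' @param c1,c2 Component concentrations (mg/L).
#' @param mw1,mw2 Component molecular weights (g/mol).
#' @param mw_total Molecular weight used to express the molar total as a mass
#'   concentration (g/mol).
#' @return Total concentration (mg/L).
#' @examples
#' pmb_total_concentration(2, 1, mw1 = 1000, mw2 = 500, mw_total = 900)
#' @export
pmb_total_concentration <- function(c1, c2, mw1 = 1203.5, mw2 = 1189.5,
                                    mw_total = 1203.5) {
  stopifnot(all(mw1 > 0), all(mw2 > 0), all(mw_total > 0))
  (c1 / mw1 + c2 / mw2) * mw_total
}
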