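#' Covariate effect specification
#'
#' One candidate covariate-parameter relationship for the power model
#' `param = typical * (cov/median)^theta`.
#'
#' @param col Covariate column name in the dataset (e.g. `"CRCL"`).
#' @param param Structural parameter the covariate acts on: `"cl"` or `"v"`.
#' @param median Centring value; `NULL` resolves to the reference median of
#'   the supplied [pk_params] for `CRCL`/`PLT` and to the dataset median
#'   otherwise.
#' @param init Initial exponent; `NULL` resolves to the [pk_params] exponent
#'   for the reference CrCL/PLT-on-CL effects and to 0 otherwise.
#' @return A list of class `cov_effect`.
#' @examples
#' cov_effect("CRCL", "cl")
#' @export
cov_effect <- function(col, param = c("cl", "v"), median = NULL, init = NULL) {
  param <- match.arg(param)
  stopifnot(is.character(col), length(col) == 1L)
  structure(list(col = col, param = param, median = median, init = init),
            class = "cov_effect")
}

#' Mixed-effects model specification
#'
#' Describes which model is fitted: the covariate effects entering the
#' power model, where the random effects sit, and the numerical settings of
#' the two-level optimisation (safeguarded Newton for the per-subject modes
#' inside a derivative-free simplex for the population parameters).
#'
#' @param covariates List of [cov_effect] objects (possibly empty).
#' @param random Random-effect placement: `"cl"` or `c("cl", "v")`.
#' @param method Marginal-likelihood approximation, `"laplace"` (default) or
#'   `"agq"`.
#' @param n_nodes Quadrature nodes when `method = "agq"`.
#' @param inner_tol Gradient tolerance of the inner (per-subject mode) Newton
#'   iterations.
#' @param outer_reltol Relative convergence tolerance of the outer simplex.
#' @param maxit Maximum outer iterations.
#' @param restarts Number of fresh-simplex restarts from the incumbent after
#'   the first optimisation (default 1; 0 speeds up replicate-heavy
#'   simulation studies).
#' @return A list of class `model_spec`.
#' @examples
#' model_spec()                      # reference CrCL + PLT on clearance
#' model_spec(covariates = list())   # base model, no covariates
#' @export
model_spec <- function(covariates = list(cov_effect("CRCL", "cl"),
                                         cov_effect("PLT", "cl")),
                       random = "cl",
                       method = c("laplace", "agq"), n_nodes = 11,
                       inner_tol = 1e-6, outer_reltol = 1e-8, maxit = 2000,
                       restarts = 1) {
  method <- match.arg(method)
  stopifnot(all(random %in% c("cl", "v")), "cl" %in% random)
  if (length(covariates) && !all(vapply(covariates, inherits, logical(1), "cov_effect"))) {
    stop("'covariates' must be a list of cov_effect objects")
  }
  structure(list(covariates = covariates, random = random, method = method,
                 n_nodes = n_nodes, inner_tol = inner_tol,
                 outer_reltol = outer_reltol, maxit = as.integer(maxit),
                 restarts = as.integer(restarts)),
            class = "model_spec")
}

# transformed-parameter bookkeeping: thetas/omegas/sigmas on the log scale to
# enforce positivity, covariate exponents unconstrained
par_from_mod <- function(mod) {
  p <- c(ltheta_cl = log(mod$theta_cl), ltheta_v = log(mod$theta_v))
  if (length(mod$beta)) p <- c(p, mod$beta)
  p <- c(p, lomega_cl = log(max(mod$omega_cl, 1e-3)))
  if ("v" %in% mod$random) p <- c(p, lomega_v = log(max(mod$omega_v, 1e-3)))
  c(p, lsigma_prop = log(max(mod$sigma_prop, 1e-4)),
    lsigma_add = log(max(mod$sigma_add, 1e-4)))
}

mod_from_par <- function(p, mod) {
  mod$theta_cl <- exp(p[["ltheta_cl"]])
  mod$theta_v <- exp(p[["ltheta_v"]])
  if (length(mod$beta)) mod$beta[] <- p[names(mod$beta)]
  mod$omega_cl <- exp(p[["lomega_cl"]])
  if ("v" %in% mod$random) mod$omega_v <- exp(p[["lomega_v"]])
  mod$sigma_prop <- exp(p[["lsigma_prop"]])
  mod$sigma_add <- exp(p[["lsigma_add"]])
  mod
}

# natural-scale estimates from a transformed vector
natural_estimates <- function(p, mod) {
  est <- c(theta_cl = exp(p[["ltheta_cl"]]), theta_v = exp(p[["ltheta_v"]]))
  if (length(mod$beta)) est <- c(est, p[names(mod$beta)])
  est <- c(est, omega_cl = exp(p[["lomega_cl"]]))
  if ("v" %in% mod$random) est <- c(est, omega_v = exp(p[["lomega_v"]]))
  c(est, sigma_prop = exp(p[["lsigma_prop"]]), sigma_add = exp(p[["lsigma_add"]]))
}

#' Fit the population pharmacokinetic model
#'
#' Maximum approximate-marginal-likelihood estimation of the one-compartment
#' infusion model: the objective is the Laplace [marginal_ofv()], minimised
#' over log-transformed population parameters by Nelder-Mead, with the
#' per-subject random-effect modes tracked by warm-started Newton iterations.
#' Standard errors come from the numerically differentiated Hessian of the
#' objective (delta method back to the natural scale); a non-positive-definite
#' Hessian flags the standard errors as unavailable rather than failing the
#' fit.
#'
#' @param data Longitudinal dataset (see [parse_pk_data()]).
#' @param spec A [model_spec].
#' @param init A [pk_params] supplying initial values (and the reference
#'   medians used to centre covariates).
#' @param fixed Character vector of transformed-parameter names held at their
#'   initial values, e.g. `c("ltheta_v", "lsigma_add")` or a covariate
#'   exponent name like `"beta_CRCL_cl"`.
#' @param se Compute standard errors (default `TRUE`; skipping them saves a
#'   Hessian evaluation in replicate-heavy simulation studies).
#' @return An object of class `pk_fit`: estimates and their SE/RSE%, the
#'   final objective function value `ofv`, empirical Bayes estimates `eta`,
#'   an observation-level prediction table `pred` (`DV`, `PRED`, `IPRED`,
#'   `IWRES`, `CWRES`, `TAD`), convergence details, and the specification
#'   used.
#' @examples
#' co <- simulate_tdm(cohort_spec(n_subjects = 12, seed = 1),
#'                    pmb_reference_params())
#' fit <- fit_poppk(co$data, model_spec(covariates = list()), se = FALSE)
#' fit$estimates
#' @export
fit_poppk <- function(data, spec = model_spec(), init = pmb_reference_params(),
                      fixed = character(), se = TRUE) {
  idx <- if (inherits(data, "pk_data_index")) data else parse_pk_data(data)
  if (length(unique(idx$obs$time)) < 2) {
    stop("design not identifiable: need at least two distinct sampling times")
  }
  mod0 <- build_mod(spec, init, idx)
  p_full <- par_from_mod(mod0)
  bad <- setdiff(fixed, names(p_full))
  if (length(bad)) stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "))
  free <- setdiff(names(p_full), fixed)
  if (!length(free)) stop("no free parameters to estimate")

  env <- new.env(parent = emptyenv())
  env$eta <- rep(0, idx$n_sub)
  objective <- function(pf) {
    p <- p_full; p[free] <- pf
    mod <- mod_from_par(p, mod0)
    out <- tryCatch(mod_ofv(idx, mod, method = spec$method,
                            n_nodes = spec$n_nodes, eta_start = env$eta),
                    error = function(e) NULL)
    if (is.null(out) || !is.finite(out$ofv)) return(1e10)
    if (!is.matrix(out$eta)) env$eta <- out$eta
    out$ofv
  }

  if (length(free) == 1L) {
    op <- stats::optim(p_full[free], objective, method = "Brent",
                       lower = p_full[free] - 6, upper = p_full[free] + 6)
  } else {
    # Nelder-Mead with restarts: a fresh simplex at the incumbent rescues the
    # occasional premature collapse
    op <- stats::optim(p_full[free], objective, method = "Nelder-Mead",
                       control = list(maxit = spec$maxit,
                                      reltol = spec$outer_reltol))
    nres <- if (is.null(spec$restarts)) 1L else spec$restarts
    for (r in seq_len(nres)) {
      op2 <- stats::optim(op$par, objective, method = "Nelder-Mead",
                          control = list(maxit = spec$maxit,
                                         reltol = spec$outer_reltol))
      if (op2$value <= op$value) {
        op2$counts <- op$counts + op2$counts
        op <- op2
      }
    }
  }
  p_hat <- p_full; p_hat[free] <- op$par
  mod_hat <- mod_from_par(p_hat, mod0)
  est <- natural_estimates(p_hat, mod_hat)

  se_nat <- rse <- rep(NA_real_, length(est)); names(se_nat) <- names(rse) <- names(est)
  vcov_t <- NULL
  if (se) {
    H <- tryCatch(stats::optimHess(op$par, objective), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(2 * solve(H), error = function(e) NULL)  # OFV = -2 logL
      if (!is.null(V) && all(is.finite(diag(V))) && all(diag(V) > 0)) {
        se_t <- sqrt(diag(V)); names(se_t) <- free
        vcov_t <- V
        for (nm in free) {
          nat_nm <- sub("^l", "", nm)
          if (startsWith(nm, "beta_")) {
            se_nat[nm] <- se_t[nm]
          } else if (nat_nm %in% names(est)) {
            se_nat[nat_nm] <- se_t[nm] * est[nat_nm]  # delta method, log scale
          }
        }
        rse <- 100 * abs(se_nat / est)
      }
    }
  }

  final <- mod_ofv(idx, mod_hat, method = spec$method, n_nodes = spec$n_nodes,
                   eta_start = env$eta)
  typ <- typical_values(idx, mod_hat)
  pred0 <- predict_f(idx, typ$cl, typ$v)
  if (is.matrix(final$eta)) {
    cl_i <- typ$cl * exp(final$eta[, 1]); v_i <- typ$v * exp(final$eta[, 2])
    eta_df <- data.frame(ID = idx$ids, eta_cl = final$eta[, 1],
                         eta_v = final$eta[, 2], cl = cl_i, v = v_i)
  } else {
    cl_i <- typ$cl * exp(final$eta); v_i <- typ$v
    eta_df <- data.frame(ID = idx$ids, eta_cl = final$eta, cl = cl_i, v = v_i)
  }
  ipred <- predict_f(idx, cl_i, v_i)
  v_ip <- pmax(mod_hat$sigma_prop^2 * ipred^2 + mod_hat$sigma_add^2, 1e-12)
  v_p <- pmax(mod_hat$sigma_prop^2 * pred0^2 + mod_hat$sigma_add^2, 1e-12)
  pred <- data.frame(ID = idx$ids[idx$obs_sub], TIME = idx$obs$time,
                     TAD = idx$tad, DV = idx$y, PRED = pred0, IPRED = ipred,
                     IWRES = (idx$y - ipred) / sqrt(v_ip),
                     CWRES = (idx$y - pred0) / sqrt(v_p))

  structure(list(estimates = est, se = se_nat, rse = rse, ofv = op$value,
                 eta = eta_df, pred = pred,
                 convergence = list(code = op$convergence,
                                    evaluations = op$counts[["function"]],
                                    message = if (op$convergence == 0) "converged"
                                              else "iteration limit reached"),
                 spec = spec, fixed = fixed, init = init,
                 par = p_hat, free = free, vcov = vcov_t,
                 n_sub = idx$n_sub, n_obs = idx$n_obs),
            class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("Population PK fit: %d subjects, %d observations, OFV %.3f (%s)\n",
              x$n_sub, x$n_obs, x$ofv, x$convergence$message))
  tab <- data.frame(Estimate = signif(x$estimates, 4),
                    `RSE%` = round(x$rse, 1), check.names = FALSE)
  print(tab)
  invisible(x)
}

#' Coerce a fitted model to a parameter set
#'
#' Maps a [fit_poppk()] result with the reference covariate structure
#' (CrCL/PLT power terms on clearance) back onto a [pk_params] object, e.g.
#' to feed the dosing simulator or the diagnostics.
#'
#' @param fit A `pk_fit`.
#' @return A [pk_params].
#' @export
as_pk_params <- function(fit) {
  stopifnot(inherits(fit, "pk_fit"))
  est <- fit$estimates
  mod <- build_mod(fit$spec, fit$init, list(covs = matrix(numeric(0), 0, 0),
                                            n_sub = 0))
  getb <- function(nm) if (nm %in% names(est)) unname(est[nm]) else 0
  med <- function(col, default) {
    j <- which(mod$beta_col == col & mod$beta_param == "cl")
    if (length(j)) mod$beta_median[j[1]] else default
  }
  pk_params(theta_cl = unname(est["theta_cl"]), theta_v = unname(est["theta_v"]),
            exp_crcl = getb("beta_CRCL_cl"), exp_plt = getb("beta_PLT_cl"),
            omega_cl = unname(est["omega_cl"]),
            omega_v = if ("omega_v" %in% names(est)) unname(est["omega_v"]) else 0,
            sigma_prop = unname(est["sigma_prop"]),
            sigma_add = unname(est["sigma_add"]),
            crcl_median = med("CRCL", fit$init$crcl_median),
            plt_median = med("PLT", fit$init$plt_median))
}

# pk_params carrying a fit's estimates, used to warm-start nested refits
params_from_fit <- function(fit) as_pk_params(fit)

#' Stepwise covariate model building
#'
#' Greedy forward addition followed by backward elimination on the power
#' covariate model. At each forward round every remaining candidate is added
#' to the current model in turn; the candidate with the largest drop in
#' objective function value is accepted if the drop exceeds `forward`
#' (3.84 = chi-square(1) at p 0.05). Backward elimination then removes, one
#' at a time, any retained covariate whose deletion raises the objective by
#' at most `backward` (6.63 = chi-square(1) at p 0.01). Candidates whose fit
#' fails are skipped with a warning.
#'
#' @param data Longitudinal dataset.
#' @param base_spec [model_spec] of the starting model (typically without
#'   covariates).
#' @param candidates List of [cov_effect] candidates; their `init` defaults
#'   to 0 here (a newly introduced covariate starts with no effect).
#' @param init Initial [pk_params] for the base fit.
#' @param forward,backward Objective-function-change thresholds.
#' @param fixed Passed through to [fit_poppk()].
#' @param se Compute standard errors for the final model only.
#' @return A list with `trace` (a data.frame of every evaluated step:
#'   covariate, direction, delta OFV, accepted flag), `fit` (final
#'   [fit_poppk()] object) and `spec` (final [model_spec]).
#' @examples
#' \donttest{
#' co <- simulate_tdm(cohort_spec(n_subjects = 40, seed = 2),
#'                    pmb_reference_params())
#' sel <- covariate_search(co$data, model_spec(covariates = list()),
#'                         list(cov_effect("CRCL", "cl")), se = FALSE)
#' sel$trace
#' }
#' @export
covariate_search <- function(data, base_spec = model_spec(covariates = list()),
                             candidates = list(cov_effect("CRCL", "cl"),
                                               cov_effect("PLT", "cl")),
                             init = pmb_reference_params(),
                             forward = 3.84, backward = 6.63,
                             fixed = character(), se = FALSE) {
  idx <- if (inherits(data, "pk_data_index")) data else parse_pk_data(data)
  candidates <- lapply(candidates, function(ce) {
    if (is.null(ce$init)) ce$init <- 0
    ce
  })
  cand_name <- vapply(candidates, function(ce) paste0(ce$col, "->", ce$param),
                      character(1))
  respec <- function(covs) {
    s <- base_spec; s$covariates <- covs; s
  }
  current <- fit_poppk(idx, base_spec, init, fixed = fixed, se = FALSE)
  retained <- list()
  trace <- list()
  remaining <- seq_along(candidates)

  repeat {  # forward addition
    if (!length(remaining)) break
    dofv <- rep(NA_real_, length(remaining))
    fits <- vector("list", length(remaining))
    for (j in seq_along(remaining)) {
      ce <- candidates[[remaining[j]]]
      f <- tryCatch(fit_poppk(idx, respec(c(retained, list(ce))),
                              params_from_fit(current), fixed = fixed,
                              se = FALSE),
                    error = function(e) NULL)
      if (is.null(f)) {
        warning("forward step failed for candidate ", cand_name[remaining[j]])
        next
      }
      fits[[j]] <- f
      dofv[j] <- current$ofv - f$ofv
    }
    best <- which.max(dofv)  # ties broken by candidate order
    acc <- length(best) > 0 && is.finite(dofv[best]) && dofv[best] > forward
    for (j in seq_along(remaining)) {
      trace[[length(trace) + 1]] <- data.frame(
        covariate = cand_name[remaining[j]], direction = "forward",
        delta_ofv = dofv[j], accepted = acc && j == best)
    }
    if (!acc) break
    retained <- c(retained, list(candidates[[remaining[best]]]))
    current <- fits[[best]]
    remaining <- remaining[-best]
  }

  repeat {  # backward elimination
    if (!length(retained)) break
    ret_name <- vapply(retained, function(ce) paste0(ce$col, "->", ce$param),
                       character(1))
    incr <- rep(NA_real_, length(retained))
    fits <- vector("list", length(retained))
    for (j in seq_along(retained)) {
      f <- tryCatch(fit_poppk(idx, respec(retained[-j]),
                              params_from_fit(current), fixed = fixed,
                              se = FALSE),
                    error = function(e) NULL)
      if (is.null(f)) {
        warning("backward step failed when removing ", ret_name[j])
        next
      }
      fits[[j]] <- f
      incr[j] <- f$ofv - current$ofv
    }
    drop_j <- which.min(incr)
    rem <- length(drop_j) > 0 && is.finite(incr[drop_j]) && incr[drop_j] <= backward
    for (j in seq_along(retained)) {
      trace[[length(trace) + 1]] <- data.frame(
        covariate = ret_name[j], direction = "backward",
        delta_ofv = incr[j], accepted = rem && j == drop_j)
    }
    if (!rem) break
    current <- fits[[drop_j]]
    retained <- retained[-drop_j]
  }

  final_spec <- respec(retained)
  final <- if (se) fit_poppk(idx, final_spec, params_from_fit(current),
                             fixed = fixed, se = TRUE) else current
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(covariate = character(), direction = character(),
               delta_ofv = numeric(), accepted = logical())
  list(trace = trace, fit = final, spec = final_spec)
}

#' Nonparametric bootstrap of the population model
#'
#' Resamples subjects with replacement, refits the model on each replicate
#' (warm-started at the original estimates) and summarises the replicate
#' estimates by their median and 2.5-97.5 percentile interval. Replicates
#' whose fit fails are counted and excluded; more than 20% failures raises a
#' warning.
#'
#' @param data Longitudinal dataset.
#' @param spec [model_spec] of the model being bootstrapped.
#' @param init [pk_params] starting values (typically the original
#'   estimates, see [as_pk_params()]).
#' @param n_boot Number of bootstrap replicates.
#' @param seed Seed controlling the resample indices; identical seeds give
#'   identical resamples.
#' @param fixed,maxit Passed to the replicate fits (`maxit` deliberately
#'   smaller than a full fit since replicates start near the solution).
#' @return An object of class `pk_boot` with the replicate `estimates`
#'   matrix, a `summary` table (median, 2.5 and 97.5 percentiles), the
#'   resample index matrix and the failure count.
#' @export
bootstrap_poppk <- function(data, spec = model_spec(),
                            init = pmb_reference_params(), n_boot = 200,
                            seed = 1, fixed = character(), maxit = 600) {
  stopifnot(n_boot >= 1)
  df <- if (inherits(data, "pk_data_index")) stop("bootstrap needs the raw dataset") else data
  ids <- unique(df$ID)
  by_id <- split(df, df$ID)
  set.seed(seed)
  samples <- matrix(sample(length(ids), length(ids) * n_boot, replace = TRUE),
                    nrow = n_boot)
  spec$maxit <- as.integer(maxit)
  est_list <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    pick <- samples[b, ]
    rd <- do.call(rbind, lapply(seq_along(pick), function(k) {
      block <- by_id[[pick[k]]]
      block$ID <- k
      block
    }))
    f <- tryCatch(fit_poppk(rd, spec, init, fixed = fixed, se = FALSE),
                  error = function(e) NULL)
    if (!is.null(f) && f$convergence$code %in% c(0L, 1L)) {
      est_list[[b]] <- f$estimates
    }
  }
  ok <- !vapply(est_list, is.null, logical(1))
  n_failed <- sum(!ok)
  if (n_failed > 0.2 * n_boot) {
    warning(sprintf("%d of %d bootstrap replicates failed", n_failed, n_boot))
  }
  est <- do.call(rbind, est_list[ok])
  summ <- data.frame(
    parameter = colnames(est),
    median = apply(est, 2, stats::median),
    lower = apply(est, 2, stats::quantile, probs = 0.025),
    upper = apply(est, 2, stats::quantile, probs = 0.975),
    row.names = NULL)
  structure(list(estimates = est, summary = summ, samples = samples,
                 n_boot = n_boot, n_failed = n_failed, seed = seed),
            class = "pk_boot")
}

#' @export
print.pk_boot <- function(x, ...) {
  cat(sprintf("Bootstrap: %d replicates (%d failed)\n", x$n_boot, x$n_failed))
  print(transform(x$summary, median = signif(median, 4),
                  lower = signif(lower, 4), upper = signif(upper, 4)))
  invisible(x)
}
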