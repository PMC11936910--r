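# Internal machinery for the nonlinear mixed-effects likelihood.
#
# A parsed dataset is flattened into a dose-by-observation "long" table so
# that one model evaluation is a handful of vectorised operations over that
# table, whatever the per-subject dosing histories look like. The marginal
# likelihood integrates the subject-level random effects by a Laplace
# expansion about the per-subject posterior modes (empirical Bayes
# estimates), with the residual variance evaluated at the individual
# predictions -- the standard "with interaction" conditional scheme -- and an
# adaptive Gauss-Hermite alternative for cross-checking the approximation.

PK_RESERVED_COLS <- c("ID", "TIME", "AMT", "RATE", "DV", "EVID", "MDV", "OCC")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a longitudinal dosing/observation table
#'
#' Validates and indexes an analysis dataset in the conventional longitudinal
#' layout (`ID`, `TIME`, `AMT`, `RATE`, `DV`, `EVID`, `MDV`, plus covariate
#' columns). Dose records have `EVID = 1` with infusion duration `AMT/RATE`;
#' observation records have `EVID = 0`, `MDV = 0`. A record's concentration
#' is predicted by superposing all infusions started strictly before its
#' time, so a pre-dose trough that shares its timestamp with a dose record
#' excludes that dose.
#'
#' @param data A data.frame in the layout above.
#' @return An opaque index object of class `pk_data_index` used by the
#'   estimation functions.
#' @keywords internal
#' @export
parse_pk_data <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("ID", "TIME", "AMT", "DV", "EVID")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("dataset lacks column(s): ", paste(miss, collapse = ", "))
  if (!"MDV" %in% names(data)) data$MDV <- ifelse(data$EVID == 0, 0L, 1L)
  if (!"RATE" %in% names(data)) data$RATE <- ifelse(data$EVID == 1, data$AMT, 0)

  ids <- unique(data$ID)
  n_sub <- length(ids)
  sub_of <- match(data$ID, ids)

  is_obs <- data$EVID == 0 & data$MDV == 0
  is_dose <- data$EVID == 1
  if (!any(is_obs)) stop("dataset contains no observations")
  if (any(is_obs & !is.finite(data$DV))) stop("non-finite DV on an observation record")

  obs <- data.frame(sub = sub_of[is_obs], time = data$TIME[is_obs],
                    y = data$DV[is_obs])
  n_obs <- nrow(obs)

  dose <- data.frame(sub = sub_of[is_dose], time = data$TIME[is_dose],
                     amt = data$AMT[is_dose], rate = data$RATE[is_dose])
  if (any(dose$amt <= 0)) stop("dose records must have positive AMT")
  dose$dur <- ifelse(dose$rate > 0, dose$amt / dose$rate, 1e-6)

  # long table: one row per (observation, earlier dose of the same subject)
  dose_by_sub <- split(seq_len(nrow(dose)), dose$sub)
  long <- vector("list", n_obs)
  for (o in seq_len(n_obs)) {
    dd <- dose_by_sub[[as.character(obs$sub[o])]]
    if (is.null(dd)) next
    dd <- dd[dose$time[dd] < obs$time[o]]
    if (!length(dd)) next
    long[[o]] <- data.frame(row_obs = o, row_sub = obs$sub[o],
                            amt = dose$amt[dd], dur = dose$dur[dd],
                            rel = obs$time[o] - dose$time[dd])
  }
  long <- do.call(rbind, long)
  if (is.null(long)) long <- data.frame(row_obs = integer(), row_sub = integer(),
                                        amt = numeric(), dur = numeric(),
                                        rel = numeric())

  cov_cols <- setdiff(names(data), c(PK_RESERVED_COLS))
  cov_cols <- cov_cols[vapply(data[cov_cols], is.numeric, logical(1))]
  covs <- matrix(NA_real_, n_sub, length(cov_cols),
                 dimnames = list(NULL, cov_cols))
  first_row <- match(seq_len(n_sub), sub_of)
  for (cc in cov_cols) covs[, cc] <- data[[cc]][first_row]

  # time after the most recent dose, for diagnostics
  tad <- rep(NA_real_, n_obs)
  if (nrow(long)) {
    mins <- tapply(long$rel, long$row_obs, min)
    tad[as.integer(names(mins))] <- as.numeric(mins)
  }

  structure(list(ids = ids, n_sub = n_sub, n_obs = n_obs,
                 obs = obs, obs_sub = obs$sub, y = obs$y, tad = tad,
                 long = long, covs = covs),
            class = "pk_data_index")
}

# per-observation concentration prediction given per-subject cl and v
predict_f <- function(idx, cl_sub, v_sub) {
  f <- numeric(idx$n_obs)
  lg <- idx$long
  if (!nrow(lg)) return(f)
  ke <- cl_sub / v_sub
  k <- ke[lg$row_sub]
  contrib <- (lg$amt / (lg$dur * cl_sub[lg$row_sub])) *
    (-expm1(-k * pmin(lg$rel, lg$dur))) * exp(-k * pmax(lg$rel - lg$dur, 0))
  rs <- rowsum(contrib, lg$row_obs)
  f[as.integer(rownames(rs))] <- rs[, 1]
  f
}

# -2 log-likelihood contributions of the observations (no prior), summed per
# subject, with residual variance at the supplied predictions ("interaction")
obs_nll_by_sub <- function(idx, f, sigma_prop, sigma_add) {
  v <- pmax(sigma_prop^2 * f^2 + sigma_add^2, 1e-12)
  term <- 0.5 * log(2 * pi * v) + 0.5 * (idx$y - f)^2 / v
  out <- numeric(idx$n_sub)
  rs <- rowsum(term, idx$obs_sub)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

# typical (eta = 0) parameter value per subject under the covariate model
typical_values <- function(idx, mod) {
  cl <- rep(mod$theta_cl, idx$n_sub)
  v <- rep(mod$theta_v, idx$n_sub)
  if (length(mod$beta)) {
    for (j in seq_along(mod$beta)) {
      col <- mod$beta_col[j]
      if (!col %in% colnames(idx$covs)) {
        stop("covariate column '", col, "' not found in dataset")
      }
      fac <- (idx$covs[, col] / mod$beta_median[j])^mod$beta[j]
      if (mod$beta_param[j] == "cl") cl <- cl * fac else v <- v * fac
    }
  }
  list(cl = cl, v = v)
}

# vectorised safeguarded Newton minimisation of independent 1-D functions
# nlj: function(eta_vector) -> per-subject objective values
ebe_newton <- function(nlj, eta0, h = 1e-3, tol = 1e-6, maxit = 40) {
  eta <- eta0
  f0 <- nlj(eta)
  for (it in seq_len(maxit)) {
    fp <- nlj(eta + h); fm <- nlj(eta - h)
    g <- (fp - fm) / (2 * h)
    hess <- pmax((fp - 2 * f0 + fm) / h^2, 1e-8)
    conv <- abs(g) < tol
    if (all(conv)) break
    step <- pmin(pmax(-g / hess, -2), 2)
    lam <- rep(1, length(eta))
    for (ls in 1:25) {
      f_new <- nlj(eta + lam * step)
      bad <- !conv & (f_new > f0 + 1e-10)
      if (!any(bad)) break
      lam[bad] <- lam[bad] / 2
    }
    eta <- ifelse(conv, eta, eta + lam * step)
    f0 <- nlj(eta)
  }
  fp <- nlj(eta + h); fm <- nlj(eta - h)
  list(eta = eta, nlj = f0,
       grad = (fp - fm) / (2 * h),
       hess = pmax((fp - 2 * f0 + fm) / h^2, 1e-8))
}

# per-subject joint -log density as a function of eta_cl (d = 1 path)
make_nlj_cl <- function(idx, mod, typ) {
  om2 <- mod$omega_cl^2
  function(eta) {
    cl <- typ$cl * exp(eta)
    f <- predict_f(idx, cl, typ$v)
    obs_nll_by_sub(idx, f, mod$sigma_prop, mod$sigma_add) +
      0.5 * log(2 * pi * om2) + 0.5 * eta^2 / om2
  }
}

# Laplace (or fixed-effects, when omega is 0) marginal -2 log likelihood
laplace_ofv_cl <- function(idx, mod, eta_start = NULL) {
  typ <- typical_values(idx, mod)
  if (mod$omega_cl < 1e-8) {
    f <- predict_f(idx, typ$cl, typ$v)
    v <- pmax(mod$sigma_prop^2 * f^2 + mod$sigma_add^2, 1e-12)
    return(list(ofv = sum(log(2 * pi * v) + (idx$y - f)^2 / v),
                eta = rep(0, idx$n_sub),
                hess = rep(NA_real_, idx$n_sub)))
  }
  nlj <- make_nlj_cl(idx, mod, typ)
  eta0 <- if (is.null(eta_start)) rep(0, idx$n_sub) else eta_start
  nr <- ebe_newton(nlj, eta0, tol = mod$inner_tol %||% 1e-6)
  list(ofv = sum(2 * nr$nlj) - idx$n_sub * log(2 * pi) + sum(log(nr$hess)),
       eta = nr$eta, hess = nr$hess)
}

# adaptive Gauss-Hermite marginal -2 log likelihood (single random effect)
agq_ofv_cl <- function(idx, mod, n_nodes = 64) {
  typ <- typical_values(idx, mod)
  if (mod$omega_cl < 1e-8) return(laplace_ofv_cl(idx, mod))
  nlj <- make_nlj_cl(idx, mod, typ)
  nr <- ebe_newton(nlj, rep(0, idx$n_sub), tol = mod$inner_tol %||% 1e-6)
  gh <- pracma::gaussHermite(n_nodes)
  scale <- sqrt(2 / nr$hess)
  logterms <- matrix(NA_real_, idx$n_sub, n_nodes)
  for (k in seq_len(n_nodes)) {
    eta_k <- nr$eta + scale * gh$x[k]
    logterms[, k] <- -nlj(eta_k) + gh$x[k]^2 + log(gh$w[k]) + log(scale)
  }
  m <- apply(logterms, 1, max)
  loglik <- m + log(rowSums(exp(logterms - m)))
  list(ofv = -2 * sum(loglik), eta = nr$eta, hess = nr$hess)
}

# general path: random effects on CL and V, per-subject 2-D Laplace
laplace_ofv_clv <- function(idx, mod) {
  typ <- typical_values(idx, mod)
  om <- c(mod$omega_cl, mod$omega_v)
  if (all(om < 1e-8)) return(laplace_ofv_cl(idx, mod))
  om <- pmax(om, 1e-6)
  ofv <- 0
  eta_mat <- matrix(0, idx$n_sub, 2)
  sub_obs <- split(seq_len(idx$n_obs), idx$obs_sub)
  sub_long <- split(seq_len(nrow(idx$long)), idx$long$row_sub)
  for (s in seq_len(idx$n_sub)) {
    oo <- sub_obs[[as.character(s)]]
    nlj_s <- function(eta) {
      cl <- typ$cl[s] * exp(eta[1]); v <- typ$v[s] * exp(eta[2])
      fs <- numeric(length(oo))
      ll <- sub_long[[as.character(s)]]
      if (!is.null(ll)) {
        lg <- idx$long[ll, ]
        ke <- cl / v
        contrib <- (lg$amt / (lg$dur * cl)) *
          (-expm1(-ke * pmin(lg$rel, lg$dur))) * exp(-ke * pmax(lg$rel - lg$dur, 0))
        rs <- rowsum(contrib, match(lg$row_obs, oo))
        fs[as.integer(rownames(rs))] <- rs[, 1]
      }
      vv <- pmax(mod$sigma_prop^2 * fs^2 + mod$sigma_add^2, 1e-12)
      res <- if (is.null(oo)) 0 else
        sum(0.5 * log(2 * pi * vv) + 0.5 * (idx$y[oo] - fs)^2 / vv)
      res + sum(0.5 * log(2 * pi * om^2) + 0.5 * eta^2 / om^2)
    }
    op <- stats::nlminb(c(0, 0), nlj_s)
    H <- stats::optimHess(op$par, nlj_s)
    detH <- max(det(H), 1e-12)
    ofv <- ofv + 2 * op$objective - 2 * log(2 * pi) + log(detH)
    eta_mat[s, ] <- op$par
  }
  list(ofv = ofv, eta = eta_mat, hess = NULL)
}

# build the internal model list from a pk_params + model_spec pair
build_mod <- function(spec, params, idx) {
  covs <- spec$covariates
  beta <- numeric(0); bcol <- character(0); bpar <- character(0); bmed <- numeric(0)
  for (ce in covs) {
    med <- ce$median
    if (is.null(med)) {
      med <- switch(ce$col,
                    CRCL = params$crcl_median,
                    PLT = params$plt_median,
                    stats::median(idx$covs[, ce$col]))
    }
    ini <- ce$init
    if (is.null(ini)) {
      ini <- switch(paste(ce$col, ce$param, sep = "."),
                    CRCL.cl = params$exp_crcl,
                    PLT.cl = params$exp_plt,
                    0)
    }
    beta <- c(beta, ini); bcol <- c(bcol, ce$col)
    bpar <- c(bpar, ce$param); bmed <- c(bmed, med)
  }
  names(beta) <- if (length(beta)) paste0("beta_", bcol, "_", bpar) else character(0)
  list(theta_cl = params$theta_cl, theta_v = params$theta_v,
       beta = beta, beta_col = bcol, beta_param = bpar, beta_median = bmed,
       omega_cl = if ("cl" %in% spec$random) params$omega_cl else 0,
       omega_v = if ("v" %in% spec$random) params$omega_v else 0,
       sigma_prop = params$sigma_prop, sigma_add = params$sigma_add,
       random = spec$random, inner_tol = spec$inner_tol %||% 1e-6)
}

mod_ofv <- function(idx, mod, method = "laplace", n_nodes = 64, eta_start = NULL) {
  if (identical(mod$random, "cl") || mod$omega_v < 1e-8) {
    if (method == "agq") agq_ofv_cl(idx, mod, n_nodes)
    else laplace_ofv_cl(idx, mod, eta_start)
  } else {
    laplace_ofv_clv(idx, mod)
  }
}

#' Marginal objective function value (-2 log likelihood)
#'
#' Evaluates the approximate marginal likelihood of a dataset under given
#' population parameters, integrating the random effects by a Laplace
#' expansion about the empirical Bayes modes (`method = "laplace"`, the
#' default, with residual variance at the individual predictions) or by
#' adaptive Gauss-Hermite quadrature (`method = "agq"`, single random
#' effect only), which serves as a high-accuracy cross-check. With
#' `omega_cl = 0` the value reduces to the fixed-effects weighted
#' least-squares deviance.
#'
#' @param data Longitudinal dataset (see [parse_pk_data()]) or a
#'   `pk_data_index`.
#' @param params A [pk_params].
#' @param spec A [model_spec]; defaults to the reference covariate structure.
#' @param method `"laplace"` or `"agq"`.
#' @param n_nodes Quadrature nodes for `"agq"`.
#' @return The objective function value (a single number).
#' @examples
#' co <- simulate_tdm(cohort_spec(n_subjects = 6, seed = 1),
#'                    pmb_reference_params())
#' marginal_ofv(co$data, pmb_reference_params())
#' @export
marginal_ofv <- function(data, params, spec = model_spec(),
                         method = c("laplace", "agq"), n_nodes = 64) {
  method <- match.arg(method)
  idx <- if (inherits(data, "pk_data_index")) data else parse_pk_data(data)
  mod <- build_mod(spec, params, idx)
  out <- mod_ofv(idx, mod, method = method, n_nodes = n_nodes)
  if (!is.finite(out$ofv)) stop("non-finite likelihood")
  out$ofv
}

#' Empirical Bayes estimates of the individual random effects
#'
#' Maximises each subject's joint density (residual likelihood times the
#' normal random-effect prior) at fixed population parameters; the posterior
#' modes are the empirical Bayes estimates (EBEs) used for individual
#' predictions, diagnostics and covariate screening. A subject without
#' observations sits at the prior mode 0.
#'
#' @inheritParams marginal_ofv
#' @return A data.frame with `ID`, `eta_cl` (and `eta_v` if that effect is in
#'   the model), and the individual `cl` and `v`.
#' @examples
#' co <- simulate_tdm(cohort_spec(n_subjects = 6, seed = 1),
#'                    pmb_reference_params())
#' map_ebe(co$data, pmb_reference_params())
#' @export
map_ebe <- function(data, params, spec = model_spec()) {
  idx <- if (inherits(data, "pk_data_index")) data else parse_pk_data(data)
  mod <- build_mod(spec, params, idx)
  typ <- typical_values(idx, mod)
  out <- mod_ofv(idx, mod)
  if (is.matrix(out$eta)) {
    data.frame(ID = idx$ids, eta_cl = out$eta[, 1], eta_v = out$eta[, 2],
               cl = typ$cl * exp(out$eta[, 1]), v = typ$v * exp(out$eta[, 2]))
  } else {
    data.frame(ID = idx$ids, eta_cl = out$eta,
               cl = typ$cl * exp(out$eta), v = typ$v)
  }
}
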