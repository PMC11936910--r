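#' External validation metrics
#'
#' Prediction-error summaries comparing model predictions with observations
#' in an external dataset:
#' \deqn{MPE\% = \frac{100}{N}\sum_i \frac{pred_i - obs_i}{obs_i}, \qquad
#'       MAPE\% = \frac{100}{N}\sum_i \frac{|pred_i - obs_i|}{obs_i},}
#' and the fractions F20 / F30 of observations whose absolute relative
#' prediction error is at most 20% / 30% (boundary inclusive). Predictive
#' performance is acceptable when MPE% lies within +/-20%, MAPE% <= 30%,
#' F20 >= 35% and F30 >= 50%.
#'
#' @param pred Predicted concentrations.
#' @param obs Observed concentrations (same length, strictly positive).
#' @param mpe_limit,mape_limit,f20_min,f30_min Acceptance thresholds (%).
#' @return An object of class `pk_validation`: `mpe_pct`, `mape_pct`,
#'   `f20_pct`, `f30_pct`, logical `pass` flags per criterion and `pass_all`.
#' @examples
#' external_validation(c(1.1, 2.2), c(1.0, 2.0))
#' @export
external_validation <- function(pred, obs, mpe_limit = 20, mape_limit = 30,
                                f20_min = 35, f30_min = 50) {
  stopifnot(length(pred) == length(obs), length(obs) >= 1)
  if (any(obs <= 0)) stop("'obs' must be strictly positive")
  rel <- (pred - obs) / obs
  mpe <- 100 * mean(rel)
  mape <- 100 * mean(abs(rel))
  # inclusive boundaries, robust to floating-point representation of the
  # relative error (a uniform +20% error must count as within 20%)
  eps <- 1e-9
  f20 <- 100 * mean(abs(rel) <= 0.20 + eps)
  f30 <- 100 * mean(abs(rel) <= 0.30 + eps)
  pass <- c(mpe = abs(mpe) <= mpe_limit + eps, mape = mape <= mape_limit + eps,
            f20 = f20 >= f20_min - eps, f30 = f30 >= f30_min - eps)
  structure(list(mpe_pct = mpe, mape_pct = mape, f20_pct = f20, f30_pct = f30,
                 pass = pass, pass_all = all(pass), n = length(obs)),
            class = "pk_validation")
}

#' @export
print.pk_validation <- function(x, ...) {
  cat(sprintf("External validation (n = %d): MPE %.2f%%, MAPE %.2f%%, F20 %.2f%%, F30 %.2f%% -> %s\n",
              x$n, x$mpe_pct, x$mape_pct, x$f20_pct, x$f30_pct,
              if (x$pass_all) "acceptable" else "NOT acceptable"))
  invisible(x)
}

# simulate replicate observation vectors under the model; returns an
# n_obs x n_sim matrix. Residual draws follow y = f(1 + e1) + e2.
simulate_dv_matrix <- function(idx, mod, n_sim, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  typ <- typical_values(idx, mod)
  out <- matrix(NA_real_, idx$n_obs, n_sim)
  for (k in seq_len(n_sim)) {
    eta_cl <- if (mod$omega_cl > 0) stats::rnorm(idx$n_sub, 0, mod$omega_cl) else 0
    eta_v <- if (mod$omega_v > 0) stats::rnorm(idx$n_sub, 0, mod$omega_v) else 0
    f <- predict_f(idx, typ$cl * exp(eta_cl), typ$v * exp(eta_v))
    e1 <- if (mod$sigma_prop > 0) stats::rnorm(idx$n_obs, 0, mod$sigma_prop) else 0
    e2 <- if (mod$sigma_add > 0) stats::rnorm(idx$n_obs, 0, mod$sigma_add) else 0
    out[, k] <- f * (1 + e1) + e2
  }
  out
}

#' Visual predictive check
#'
#' Simulates the analysis dataset repeatedly under the model and compares, in
#' each sampling-time bin, the observed percentiles with the confidence band
#' of the same percentiles across simulation replicates. A well-specified
#' model keeps the observed percentiles inside their simulated bands.
#'
#' @param data Longitudinal dataset.
#' @param params A [pk_params] (typically the final estimates).
#' @param spec A [model_spec] mapping covariates, as used in the fit.
#' @param n_sim Number of simulation replicates.
#' @param percentiles Percentiles tracked (defaults 5, 50, 95).
#' @param bin Factor assigning each observation to a bin; defaults to the
#'   distinct nominal sampling times. Empty bins are dropped with a warning.
#' @param ci Confidence level of the simulated percentile bands.
#' @param seed Seed; fixed seed gives a deterministic VPC.
#' @return An object of class `pk_vpc` with a `table` of one row per
#'   bin-percentile (observed value, band limits, simulated median) and the
#'   bin sizes.
#' @examples
#' co <- simulate_tdm(cohort_spec(n_subjects = 15, seed = 3),
#'                    pmb_reference_params())
#' vpc(co$data, pmb_reference_params(), n_sim = 50)$table
#' @export
vpc <- function(data, params, spec = model_spec(), n_sim = 1000,
                percentiles = c(5, 50, 95), bin = NULL, ci = 0.95, seed = 1) {
  idx <- if (inherits(data, "pk_data_index")) data else parse_pk_data(data)
  mod <- build_mod(spec, params, idx)
  if (is.null(bin)) bin <- factor(signif(idx$obs$time, 8))
  bin <- as.factor(bin)
  stopifnot(length(bin) == idx$n_obs)
  empty <- setdiff(levels(bin), unique(as.character(bin)))
  if (length(empty)) {
    warning("dropping empty bin(s): ", paste(empty, collapse = ", "))
    bin <- droplevels(bin)
  }
  sims <- simulate_dv_matrix(idx, mod, n_sim, seed)
  probs <- percentiles / 100
  alpha <- (1 - ci) / 2
  rows <- list()
  for (lv in levels(bin)) {
    sel <- bin == lv
    obs_q <- stats::quantile(idx$y[sel], probs, names = FALSE)
    sim_q <- apply(sims[sel, , drop = FALSE], 2, stats::quantile,
                   probs = probs, names = FALSE)
    sim_q <- matrix(sim_q, nrow = length(probs))
    for (j in seq_along(probs)) {
      band <- stats::quantile(sim_q[j, ], c(alpha, 0.5, 1 - alpha), names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        bin = lv, n = sum(sel), percentile = percentiles[j],
        observed = obs_q[j], sim_lower = band[1], sim_median = band[2],
        sim_upper = band[3],
        within = obs_q[j] >= band[1] & obs_q[j] <= band[3])
    }
  }
  structure(list(table = do.call(rbind, rows), n_sim = n_sim, ci = ci,
                 percentiles = percentiles, seed = seed),
            class = "pk_vpc")
}

#' @export
print.pk_vpc <- function(x, ...) {
  cat(sprintf("Visual predictive check (%d simulations, %.0f%% bands)\n",
              x$n_sim, 100 * x$ci))
  print(transform(x$table, observed = signif(observed, 4),
                  sim_lower = signif(sim_lower, 4),
                  sim_median = signif(sim_median, 4),
                  sim_upper = signif(sim_upper, 4)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.pk_vpc <- function(x, ...) {
  tb <- x$table
  tb$t <- as.numeric(as.character(tb$bin))
  if (any(is.na(tb$t))) tb$t <- as.integer(as.factor(tb$bin))
  graphics::plot(range(tb$t), range(c(tb$observed, tb$sim_lower, tb$sim_upper)),
                 type = "n", xlab = "time (h)", ylab = "concentration (mg/L)",
                 main = "Visual predictive check", ...)
  for (p in unique(tb$percentile)) {
    sel <- tb$percentile == p
    ord <- order(tb$t[sel])
    graphics::polygon(c(tb$t[sel][ord], rev(tb$t[sel][ord])),
                      c(tb$sim_lower[sel][ord], rev(tb$sim_upper[sel][ord])),
                      col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
    graphics::lines(tb$t[sel][ord], tb$observed[sel][ord], type = "b", pch = 19)
  }
  invisible(x)
}

# two-sided chi-square test that a sample variance equals 1
variance_test <- function(x) {
  n <- length(x)
  stat <- (n - 1) * stats::var(x)
  p <- 2 * min(stats::pchisq(stat, n - 1), stats::pchisq(stat, n - 1, lower.tail = FALSE))
  list(statistic = stat, p.value = min(p, 1))
}

#' Normalized prediction distribution errors
#'
#' Simulation-based residual diagnostic: the dataset is simulated `n_sim`
#' times under the model; within each subject the observed and simulated
#' vectors are decorrelated with the empirical mean and Cholesky factor of
#' the simulated covariance; each decorrelated observation's rank among its
#' simulated counterparts gives a prediction discrepancy that is mapped
#' through the normal quantile function. Under a correct model the NPDE are
#' standard normal, which is checked by a t-test of mean zero, a two-sided
#' chi-square (Fisher) test of variance one, a Shapiro-Wilk normality test,
#' and a Bonferroni-combined global test of the three.
#'
#' @inheritParams vpc
#' @param ridge Diagonal inflation applied to a numerically singular
#'   simulated covariance (with a warning).
#' @return An object of class `pk_npde`: an observation-level table with
#'   `npde` and the underlying discrepancies `pd`, plus a `tests` list of
#'   p-values (`t`, `variance`, `shapiro`, `global`).
#' @examples
#' co <- simulate_tdm(cohort_spec(n_subjects = 15, seed = 4),
#'                    pmb_reference_params())
#' npde(co$data, pmb_reference_params(), n_sim = 100)$tests
#' @export
npde <- function(data, params, spec = model_spec(), n_sim = 1000, seed = 1,
                 ridge = 1e-8) {
  idx <- if (inherits(data, "pk_data_index")) data else parse_pk_data(data)
  mod <- build_mod(spec, params, idx)
  sims <- simulate_dv_matrix(idx, mod, n_sim, seed)
  pd <- rep(NA_real_, idx$n_obs)
  for (s in seq_len(idx$n_sub)) {
    oo <- which(idx$obs_sub == s)
    if (!length(oo)) next
    S <- sims[oo, , drop = FALSE]
    m <- rowMeans(S)
    Sc <- S - m
    V <- tcrossprod(Sc) / (n_sim - 1)
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) {
      warning("singular simulated covariance for subject ", idx$ids[s],
              "; ridge-regularised")
      L <- chol(V + diag(ridge + max(diag(V)) * 1e-10, nrow(V)))
    }
    ystar <- backsolve(L, idx$y[oo] - m, transpose = TRUE)
    sstar <- backsolve(L, Sc, transpose = TRUE)
    pd[oo] <- (rowSums(sstar < ystar) + 0.5) / (n_sim + 1)
  }
  npde_val <- stats::qnorm(pd)
  tt <- stats::t.test(npde_val)
  vt <- variance_test(npde_val)
  sw <- stats::shapiro.test(if (length(npde_val) > 5000)
    sample(npde_val, 5000) else npde_val)
  pvals <- c(t = tt$p.value, variance = vt$p.value, shapiro = sw$p.value)
  global <- min(1, 3 * min(pvals))
  tab <- data.frame(ID = idx$ids[idx$obs_sub], TIME = idx$obs$time,
                    TAD = idx$tad, DV = idx$y, pd = pd, npde = npde_val)
  structure(list(table = tab, tests = c(pvals, global = global),
                 n_sim = n_sim, seed = seed),
            class = "pk_npde")
}

#' @export
print.pk_npde <- function(x, ...) {
  cat(sprintf("NPDE over %d observations (%d simulations)\n",
              nrow(x$table), x$n_sim))
  cat(sprintf("  mean %.3f, var %.3f\n", mean(x$table$npde), stats::var(x$table$npde)))
  cat(sprintf("  p-values: t %.3g, variance %.3g, Shapiro-Wilk %.3g, global %.3g\n",
              x$tests["t"], x$tests["variance"], x$tests["shapiro"],
              x$tests["global"]))
  invisible(x)
}

#' @export
plot.pk_npde <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2)); on.exit(graphics::par(op))
  z <- x$table$npde
  graphics::hist(z, freq = FALSE, main = "NPDE", xlab = "NPDE")
  graphics::curve(stats::dnorm(x), add = TRUE, col = "red")
  stats::qqnorm(z); stats::qqline(z, col = "red")
  graphics::plot(x$table$TIME, z, xlab = "time (h)", ylab = "NPDE",
                 main = "NPDE vs time")
  graphics::abline(h = 0, col = "red")
  graphics::plot(x$table$DV, z, xlab = "observed (mg/L)", ylab = "NPDE",
                 main = "NPDE vs concentration")
  graphics::abline(h = 0, col = "red")
  invisible(x)
}

#' Goodness-of-fit diagnostic plot
#'
#' The conventional 2x2 panel: observations against individual and population
#' predictions, and conditional weighted residuals against population
#' predictions and time after dose.
#'
#' @param x A `pk_fit`.
#' @param ... Passed to the panels.
#' @export
plot.pk_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2)); on.exit(graphics::par(op))
  p <- x$pred
  lim <- range(c(p$DV, p$IPRED, p$PRED))
  graphics::plot(p$IPRED, p$DV, xlim = lim, ylim = lim,
                 xlab = "individual prediction", ylab = "observed", ...)
  graphics::abline(0, 1, col = "red")
  graphics::plot(p$PRED, p$DV, xlim = lim, ylim = lim,
                 xlab = "population prediction", ylab = "observed", ...)
  graphics::abline(0, 1, col = "red")
  graphics::plot(p$PRED, p$CWRES, xlab = "population prediction",
                 ylab = "weighted residual", ...)
  graphics::abline(h = 0, col = "red")
  graphics::plot(p$TAD, p$CWRES, xlab = "time after dose (h)",
                 ylab = "weighted residual", ...)
  graphics::abline(h = 0, col = "red")
  invisible(x)
}
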