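#' End-to-end workflow replay on a synthetic study
#'
#' Runs the complete analysis pipeline on data the package generates itself:
#' simulate a modelling cohort and a smaller external-validation cohort from
#' the reference parameters, fit the base model, select covariates
#' stepwise, bootstrap the final model, run the visual predictive check and
#' NPDE diagnostics, externally validate on the held-out cohort, compare
#' two-point and model-based AUC estimates, and simulate the dosing grid.
#' Every stochastic stage derives its seed from `seed`, so a replay is fully
#' reproducible, and each stage is announced on the message stream.
#'
#' The defaults are sized for a laptop-scale demonstration; raise
#' `n_subjects`, `n_boot` and `n_sim` for production-quality numbers.
#'
#' @param seed Base random seed.
#' @param n_subjects Modelling-cohort size.
#' @param n_validation External-validation cohort size.
#' @param n_boot Bootstrap replicates.
#' @param n_sim Simulation replicates for VPC and NPDE.
#' @param grid_n Subjects per dosing-grid cell.
#' @param params Generating [pk_params].
#' @param out_dir Optional directory; when given, the main tables are written
#'   there as CSV files (plus a `run_info.yaml` with seed and parameter
#'   provenance).
#' @return A list of class `pmb_replay` bundling every stage's result:
#'   `cohort`, `fit` (final model), `search` trace, `parameter_table` (a
#'   final-estimate / bootstrap summary table), `boot`, `vpc`, `npde`,
#'   `validation`, `agreement`, `grid`, and `seed`.
#' @examples
#' \donttest{
#' rep <- replay_study(seed = 1, n_subjects = 30, n_boot = 5, n_sim = 100,
#'                     grid_n = 200)
#' rep$parameter_table
#' }
#' @export
replay_study <- function(seed = 1, n_subjects = 80, n_validation = 15,
                         n_boot = 200, n_sim = 500, grid_n = 1000,
                         params = pmb_reference_params(), out_dir = NULL) {
  stage <- function(...) message(sprintf("[replay] %s", sprintf(...)))

  stage("simulating modelling cohort (n = %d)", n_subjects)
  co <- simulate_tdm(cohort_spec(n_subjects = n_subjects, seed = seed), params)

  stage("fitting base model and running covariate search")
  sel <- covariate_search(co$data, model_spec(covariates = list()),
                          candidates = list(cov_effect("CRCL", "cl"),
                                            cov_effect("PLT", "cl")),
                          init = params, se = TRUE)
  fit <- sel$fit
  final_params <- as_pk_params(fit)

  stage("bootstrapping final model (%d replicates)", n_boot)
  boot <- bootstrap_poppk(co$data, sel$spec, final_params, n_boot = n_boot,
                          seed = seed + 1)
  ptab <- data.frame(parameter = names(fit$estimates),
                     estimate = unname(fit$estimates),
                     rse_pct = unname(fit$rse),
                     boot_median = boot$summary$median[
                       match(names(fit$estimates), boot$summary$parameter)],
                     boot_lower = boot$summary$lower[
                       match(names(fit$estimates), boot$summary$parameter)],
                     boot_upper = boot$summary$upper[
                       match(names(fit$estimates), boot$summary$parameter)])

  stage("model qualification: VPC and NPDE (%d simulations)", n_sim)
  vpc_res <- vpc(co$data, final_params, sel$spec, n_sim = n_sim, seed = seed + 2)
  npde_res <- npde(co$data, final_params, sel$spec, n_sim = n_sim, seed = seed + 3)

  stage("external validation on held-out cohort (n = %d)", n_validation)
  vco <- simulate_tdm(cohort_spec(n_subjects = n_validation, seed = seed + 4),
                      params)
  ipred <- individual_predictions(vco$data, final_params, sel$spec)
  ext <- external_validation(ipred$IPRED, ipred$DV)

  stage("two-point vs model-based AUC agreement")
  pairs <- cohort_auc_pairs(co, final_params, spec = sel$spec)
  agr <- auc_agreement(pairs)

  stage("dosing-grid simulation (%d subjects per cell)", grid_n)
  grid <- run_grid(final_params, n = grid_n, seed = seed + 5)

  out <- structure(list(cohort = co, fit = fit, search = sel$trace,
                        parameter_table = ptab, boot = boot, vpc = vpc_res,
                        npde = npde_res, validation = ext, agreement = agr,
                        grid = grid, params = final_params, seed = seed),
                   class = "pmb_replay")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(co$data, file.path(out_dir, "cohort.csv"), row.names = FALSE)
    utils::write.csv(ptab, file.path(out_dir, "parameter_table.csv"), row.names = FALSE)
    utils::write.csv(sel$trace, file.path(out_dir, "covariate_search.csv"), row.names = FALSE)
    utils::write.csv(vpc_res$table, file.path(out_dir, "vpc.csv"), row.names = FALSE)
    utils::write.csv(npde_res$table, file.path(out_dir, "npde.csv"), row.names = FALSE)
    utils::write.csv(pairs, file.path(out_dir, "auc_pairs.csv"), row.names = FALSE)
    utils::write.csv(grid$table, file.path(out_dir, "dosing_grid.csv"), row.names = FALSE)
    yaml::write_yaml(list(seed = seed, n_subjects = n_subjects,
                          n_validation = n_validation, n_boot = n_boot,
                          n_sim = n_sim, grid_n = grid_n,
                          params = lapply(unclass(final_params), as.numeric)),
                     file.path(out_dir, "run_info.yaml"))
  }
  out
}

#' @export
print.pmb_replay <- function(x, ...) {
  cat("Synthetic study replay (seed", x$seed, ")\n\nParameter table:\n")
  print(transform(x$parameter_table, estimate = signif(estimate, 4),
                  rse_pct = round(rse_pct, 1),
                  boot_median = signif(boot_median, 4),
                  boot_lower = signif(boot_lower, 4),
                  boot_upper = signif(boot_upper, 4)), row.names = FALSE)
  cat("\n"); print(x$validation)
  cat("\n"); print(x$agreement)
  cat("\nPer-dose mean within-window percentage:\n")
  print(x$grid$by_dose, row.names = FALSE)
  invisible(x)
}

#' Individual (empirical Bayes) predictions for a dataset
#'
#' Convenience wrapper: computes the EBEs at fixed population parameters and
#' returns the observation table with individual predictions, e.g. to
#' externally validate a model on a new cohort.
#'
#' @inheritParams marginal_ofv
#' @return A data.frame with `ID`, `TIME`, `DV`, `PRED`, `IPRED`.
#' @export
individual_predictions <- function(data, params, spec = model_spec()) {
  idx <- if (inherits(data, "pk_data_index")) data else parse_pk_data(data)
  mod <- build_mod(spec, params, idx)
  typ <- typical_values(idx, mod)
  ebe <- mod_ofv(idx, mod)
  if (is.matrix(ebe$eta)) {
    cl_i <- typ$cl * exp(ebe$eta[, 1]); v_i <- typ$v * exp(ebe$eta[, 2])
  } else {
    cl_i <- typ$cl * exp(ebe$eta); v_i <- typ$v
  }
  data.frame(ID = idx$ids[idx$obs_sub], TIME = idx$obs$time, DV = idx$y,
             PRED = predict_f(idx, typ$cl, typ$v),
             IPRED = predict_f(idx, cl_i, v_i))
}

#' Paired two-point and model-based AUC estimates for a cohort
#'
#' Builds the subject-occasion AUC comparison table from a simulated cohort:
#' the two-point estimate from each occasion's observed trough/peak pair, and
#' the model-based estimate `daily dose / CL_i` with the individual clearance
#' from the empirical Bayes estimate under `params`.
#'
#' @param cohort A `pmb_cohort` from [simulate_tdm()].
#' @param params A [pk_params] used for the empirical Bayes step.
#' @param spec A [model_spec] mapping the covariates.
#' @return A data.frame (one row per subject-occasion) with `id`, `occ`,
#'   `c_trough`, `c_peak`, `auc_two_point`, `auc_model`, `flag`.
#' @examples
#' co <- simulate_tdm(cohort_spec(n_subjects = 10, seed = 5),
#'                    pmb_reference_params())
#' head(cohort_auc_pairs(co, pmb_reference_params()))
#' @export
cohort_auc_pairs <- function(cohort, params, spec = model_spec()) {
  stopifnot(inherits(cohort, "pmb_cohort"))
  obs <- cohort$obs
  reg <- cohort$regimen
  wide <- merge(
    stats::setNames(obs[obs$TYPE == "trough", c("ID", "OCC", "DV")],
                    c("id", "occ", "c_trough")),
    stats::setNames(obs[obs$TYPE == "peak", c("ID", "OCC", "DV")],
                    c("id", "occ", "c_peak")),
    by = c("id", "occ"))
  tp <- auc_two_point_table(wide, tau = reg$tau, t_inf = reg$t_inf)
  ebe <- map_ebe(cohort$data, params, spec)
  tp$auc_model <- auc_model(ebe$cl[match(tp$id, ebe$ID)],
                            reg$dose * 24 / reg$tau)
  tp[, c("id", "occ", "c_trough", "c_peak", "ke", "auc_two_point",
         "auc_model", "flag")]
}
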