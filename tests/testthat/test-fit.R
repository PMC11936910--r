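test_that("the engine recovers generating parameters on a small cohort", {
  co <- make_cohort(60, seed = 21)
  fit <- fit_poppk(co$data, model_spec(), ref_params, se = TRUE)
  expect_equal(fit$convergence$code, 0)
  expect_equal(unname(fit$estimates["theta_cl"]), 2.03, tolerance = 0.15)
  expect_equal(unname(fit$estimates["theta_v"]), 18, tolerance = 0.15)
  expect_true(all(is.finite(fit$rse)) && all(fit$rse > 0))
  expect_equal(nrow(fit$eta), 60)
  expect_equal(nrow(fit$pred), 120)
  expect_true(all(c("PRED", "IPRED", "IWRES", "CWRES", "TAD") %in% names(fit$pred)))
})

test_that("refits from perturbed starting values land on the same optimum", {
  co <- make_cohort(40, seed = 22)
  f1 <- fit_poppk(co$data, model_spec(covariates = list()), ref_params, se = FALSE)
  init2 <- pk_params(theta_cl = 2.03 * 1.2, theta_v = 18 * 0.8,
                     omega_cl = 0.385 * 1.2, sigma_prop = 0.36, sigma_add = 0.17)
  f2 <- fit_poppk(co$data, model_spec(covariates = list()), init2, se = FALSE)
  expect_lt(abs(f1$ofv - f2$ofv), 0.1)
})

test_that("fixing parameters holds them at their initial values", {
  co <- make_cohort(25, seed = 23)
  fit <- fit_poppk(co$data, model_spec(covariates = list()), ref_params,
                   fixed = c("ltheta_v", "lsigma_add"), se = FALSE)
  expect_equal(unname(fit$estimates["theta_v"]), 18)
  expect_equal(unname(fit$estimates["sigma_add"]), 0.21)
  expect_error(fit_poppk(co$data, model_spec(covariates = list()), ref_params,
                         fixed = "not_a_parameter"), "unknown fixed")
})

test_that("covariate search keeps a real effect and drops an absent one", {
  # CrCL influences clearance, platelets deliberately do not
  gen <- pk_params(exp_plt = 0)
  co <- simulate_tdm(cohort_spec(n_subjects = 80, seed = 24), gen)
  sel <- covariate_search(co$data, model_spec(covariates = list()),
                          candidates = list(cov_effect("CRCL", "cl"),
                                            cov_effect("PLT", "cl")),
                          init = ref_params)
  kept <- vapply(sel$spec$covariates, function(ce) ce$col, character(1))
  expect_true("CRCL" %in% kept)
  expect_false("PLT" %in% kept)
  expect_true(all(sel$trace$direction %in% c("forward", "backward")))
  fwd <- sel$trace[sel$trace$direction == "forward" & sel$trace$accepted, ]
  expect_true(all(fwd$delta_ofv > 3.84))
})

test_that("covariate search with no candidates returns the base fit", {
  co <- make_cohort(15, seed = 25)
  base_spec <- model_spec(covariates = list())
  sel <- covariate_search(co$data, base_spec, candidates = list(),
                          init = ref_params)
  base <- fit_poppk(co$data, base_spec, ref_params, se = FALSE)
  expect_equal(nrow(sel$trace), 0)
  expect_equal(sel$fit$ofv, base$ofv, tolerance = 1e-10)
  expect_length(sel$spec$covariates, 0)
})

test_that("bootstrap is deterministic per seed and degenerates at one replicate", {
  co <- make_cohort(30, seed = 26)
  spec <- model_spec(covariates = list())
  b1 <- bootstrap_poppk(co$data, spec, ref_params, n_boot = 3, seed = 5)
  b2 <- bootstrap_poppk(co$data, spec, ref_params, n_boot = 3, seed = 5)
  expect_identical(b1$samples, b2$samples)
  expect_equal(b1$estimates, b2$estimates, tolerance = 1e-12)
  one <- bootstrap_poppk(co$data, spec, ref_params, n_boot = 1, seed = 9)
  expect_equal(one$summary$median, one$summary$lower, tolerance = 1e-12)
  expect_equal(one$summary$median, one$summary$upper, tolerance = 1e-12)
})

test_that("bootstrap interval covers the generating typical clearance", {
  co <- make_cohort(60, seed = 27)
  fit <- fit_poppk(co$data, model_spec(), ref_params, se = FALSE)
  boot <- bootstrap_poppk(co$data, model_spec(), as_pk_params(fit),
                          n_boot = 30, seed = 11)
  expect_equal(boot$n_failed, 0)
  j <- boot$summary$parameter == "theta_cl"
  expect_lt(boot$summary$lower[j], 2.03)
  expect_gt(boot$summary$upper[j], 2.03)
  # replicate medians sit near the point estimate
  expect_equal(boot$summary$median[j], unname(fit$estimates["theta_cl"]),
               tolerance = 0.15)
})

test_that("as_pk_params round-trips a reference-structure fit", {
  co <- make_cohort(30, seed = 28)
  fit <- fit_poppk(co$data, model_spec(), ref_params, se = FALSE)
  p <- as_pk_params(fit)
  expect_s3_class(p, "pk_params")
  expect_equal(p$theta_cl, unname(fit$estimates["theta_cl"]))
  expect_equal(p$exp_crcl, unname(fit$estimates["beta_CRCL_cl"]))
  expect_equal(p$crcl_median, 75.99)
  # OFV at the converted parameters reproduces the fit's optimum
  expect_equal(marginal_ofv(co$data, p), fit$ofv, tolerance = 1e-6)
})
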