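test_that("covariate model reproduces the typical clearance and scales with eta", {
  p <- ref_params
  expect_equal(individual_clearance(p, 75.99, 163.5), 2.03, tolerance = 1e-12)
  expect_equal(individual_clearance(p, 75.99, 163.5, eta_cl = log(2)), 4.06,
               tolerance = 1e-12)
  # hand evaluation of the power law at CrCL 30, PLT 85:
  # 2.03 * (30/75.99)^0.26 * (85/163.5)^(-0.14) = 1.747128
  expect_equal(individual_clearance(p, 30, 85), 1.747128, tolerance = 1e-6)
  expect_error(individual_clearance(p, -1, 100), "positive")
  expect_error(individual_clearance(p, 100, 0), "positive")
})

test_that("clearance is monotone in CrCL (up) and PLT (down) for the reference signs", {
  p <- ref_params
  crcl <- seq(20, 180, by = 5)
  cl_crcl <- individual_clearance(p, crcl, 163.5)
  expect_true(all(diff(cl_crcl) > 0))
  plt <- seq(50, 400, by = 10)
  cl_plt <- individual_clearance(p, 75.99, plt)
  expect_true(all(diff(cl_plt) < 0))
})

test_that("steady-state infusion solution matches the closed-form peak and trough", {
  ind <- individual_pk(ref_params, 75.99, 163.5)
  reg <- regimen(75, tau = 12, t_inf = 1)
  # (R0/CL)(1 - e^(-ke*t_inf)) / (1 - e^(-ke*tau)) with CL 2.03, V 18:
  expect_equal(conc_ss(ind, reg, 1), 5.313084, tolerance = 1e-6)
  # trough is the peak decayed over tau - t_inf = 11 h
  expect_equal(conc_ss(ind, reg, 12 - 1e-12), 5.313084 * exp(-2.03 / 18 * 11),
               tolerance = 1e-6)
  # continuity at the end of the infusion
  expect_equal(conc_ss(ind, reg, 1), conc_ss(ind, reg, 1 + 1e-9),
               tolerance = 1e-6)
  expect_error(conc_ss(ind, reg, 12), "\\[0, tau\\)")
  expect_error(conc_ss(ind, reg, -0.1), "\\[0, tau\\)")
})

test_that("continuous-infusion limit plateaus at R0/CL", {
  ind <- individual_pk(ref_params, 75.99, 163.5)
  reg <- regimen(75, tau = 12, t_inf = 12 - 1e-6)
  r0 <- 75 / reg$t_inf
  expect_equal(conc_ss(ind, reg, 12 - 1e-5), r0 / ind$cl, tolerance = 1e-3)
})

test_that("concentrations and AUC are dose-proportional", {
  ind <- individual_pk(ref_params, 60, 120, eta_cl = 0.3)
  t <- c(0.5, 1, 3, 11.9)
  r1 <- regimen(75, 12, 1); r2 <- regimen(150, 12, 1)
  expect_equal(conc_ss(ind, r2, t), 2 * conc_ss(ind, r1, t), tolerance = 1e-12)
  r1l <- regimen(75, 12, 1, n_doses = 4, loading_dose = 150)
  r2l <- regimen(150, 12, 1, n_doses = 4, loading_dose = 300)
  tt <- c(0.5, 5, 13, 40)
  expect_equal(conc_superposition(ind, r2l, tt),
               2 * conc_superposition(ind, r1l, tt), tolerance = 1e-12)
  expect_equal(auc_model(ind$cl, 300), 2 * auc_model(ind$cl, 150))
})

test_that("AUC over one interval integrates to daily dose / CL", {
  ind <- individual_pk(ref_params, 75.99, 163.5)
  reg <- regimen(75, tau = 12, t_inf = 1)
  q <- integrate(function(t) conc_ss(ind, reg, t), 0, 12 - 1e-12,
                 rel.tol = 1e-10, subdivisions = 500L)
  expect_equal(q$value * (24 / 12), auc_model(ind$cl, 150), tolerance = 1e-6)
})

test_that("superposition reduces to a single infusion and converges to steady state", {
  ind <- individual_pk(ref_params, 75.99, 163.5)
  reg1 <- regimen(75, 12, 1, n_doses = 1)
  ke <- ind$ke
  t <- 5
  single <- (75 / 1 / ind$cl) * (1 - exp(-ke * 1)) * exp(-ke * (t - 1))
  expect_equal(conc_superposition(ind, reg1, t), single, tolerance = 1e-12)
  # after 20 doses the profile is numerically at steady state (ke*tau ~ 1.35)
  reg20 <- regimen(75, 12, 1, n_doses = 20)
  for (tt in c(0.5, 1, 6, 11.5)) {
    expect_equal(conc_superposition(ind, reg20, 19 * 12 + tt),
                 conc_ss(ind, reg1, tt), tolerance = 1e-8)
  }
  # 4 prior doses put the peak within 1% of the plateau
  reg5 <- regimen(75, 12, 1, n_doses = 5)
  expect_equal(conc_superposition(ind, reg5, 4 * 12 + 1),
               conc_ss(ind, reg1, 1), tolerance = 0.01)
})

test_that("a loading dose raises early concentrations but not steady state", {
  ind <- individual_pk(ref_params, 75.99, 163.5)
  plain <- regimen(75, 12, 1, n_doses = 20)
  loaded <- regimen(75, 12, 1, n_doses = 20, loading_dose = 150)
  expect_gt(conc_superposition(ind, loaded, 2),
            conc_superposition(ind, plain, 2))
  expect_equal(conc_superposition(ind, loaded, 19 * 12 + 1),
               conc_superposition(ind, plain, 19 * 12 + 1), tolerance = 1e-6)
})

test_that("auc_model validates and computes the quotient", {
  expect_equal(auc_model(2.03, 150), 150 / 2.03)
  expect_equal(auc_model(1, 100), 100)
  expect_error(auc_model(0, 100), "positive")
  expect_error(auc_model(-2, 100), "positive")
})
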