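test_that("Bland-Altman statistics match hand arithmetic", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$mean_bias, 0)
  expect_equal(c(ba0$lower, ba0$upper), c(0, 0))
  ba5 <- bland_altman(c(6, 7, 8), c(1, 2, 3))
  expect_equal(ba5$mean_bias, 5)
  expect_equal(ba5$sd_diff, 0)
  # d = {-2, +2}: mean 0, sd 2.828, limits +/- 5.544
  ba <- bland_altman(c(8, 12), c(10, 10))
  expect_equal(ba$mean_bias, 0)
  expect_equal(ba$sd_diff, 2.828427, tolerance = 1e-6)
  expect_equal(ba$upper, 5.543717, tolerance = 1e-6)
  expect_equal(ba$lower, -5.543717, tolerance = 1e-6)
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("Bland-Altman limits contain about 95% of normal differences", {
  set.seed(71)
  y <- rlnorm(2000, 4, 0.3)
  x <- y + rnorm(2000, 3, 5)
  ba <- bland_altman(x, y)
  expect_gt(ba$pct_within, 93)
  expect_lt(ba$pct_within, 97)
})

# pairs of AUC vectors realising a given inside/outside 2x2 count table
pairs_from_counts <- function(a, b, cc, d) {
  inside <- 75; outside <- 150
  x <- c(rep(inside, a + b), rep(outside, cc + d))
  y <- c(rep(inside, a), rep(outside, b), rep(inside, cc), rep(outside, d))
  list(x = x, y = y)
}

test_that("kappa is 1 for perfect agreement and 0 for independent classifications", {
  pp <- pairs_from_counts(40, 0, 0, 40)
  expect_equal(window_kappa(pp$x, pp$y)$kappa, 1)
  # margins exactly independent: (9, 21, 6, 14) gives p_o = p_e = 0.46
  pi <- pairs_from_counts(9, 21, 6, 14)
  expect_equal(window_kappa(pi$x, pi$y)$kappa, 0, tolerance = 1e-12)
})

test_that("kappa matches the hand formula and an independent implementation", {
  pp <- pairs_from_counts(40, 10, 5, 45)
  k <- window_kappa(pp$x, pp$y)
  # p_o = 0.85, p_e = 0.5 * 0.45 + 0.5 * 0.55 = 0.5 -> kappa = 0.7
  expect_equal(k$p_o, 0.85)
  expect_equal(k$p_e, 0.5)
  expect_equal(k$kappa, 0.7, tolerance = 1e-12)
  skip_if_not_installed("e1071")
  expect_equal(k$kappa, e1071::classAgreement(k$table)$kappa, tolerance = 1e-12)
})

test_that("degenerate identical constant classifications are flagged", {
  k <- window_kappa(c(60, 70, 80), c(65, 75, 85))
  expect_true(k$degenerate)
  expect_equal(k$kappa, 1)
})

test_that("McNemar uses the exact binomial form for few discordant pairs", {
  pp <- pairs_from_counts(20, 10, 3, 20)
  m <- mcnemar_window(pp$x, pp$y)
  expect_equal(m$method, "exact binomial")
  # enumeration oracle: two-sided binomial tail for (10, 3)
  p_exact <- 2 * sum(choose(13, 10:13)) / 2^13
  expect_equal(m$p.value, p_exact, tolerance = 1e-12)
})

test_that("McNemar continuity-corrected form is symmetric and calibrated", {
  pp <- pairs_from_counts(20, 15, 15, 20)
  m <- mcnemar_window(pp$x, pp$y)
  expect_equal(m$method, "chi-square, continuity-corrected")
  expect_gt(m$p.value, 0.5)
  # asymmetric discordance: corrected statistic (|b - c| - 1)^2 / (b + c)
  pa <- pairs_from_counts(10, 35, 20, 10)
  ma <- mcnemar_window(pa$x, pa$y)
  expect_equal(ma$statistic, (abs(35 - 20) - 1)^2 / 55, tolerance = 1e-12)
  all_conc <- pairs_from_counts(30, 0, 0, 30)
  m0 <- mcnemar_window(all_conc$x, all_conc$y)
  expect_equal(m0$p.value, 1)
  expect_equal(m0$method, "no discordant pairs")
})

test_that("noise-free bolus-limit cohort gives exact method agreement", {
  p0 <- quiet_params()
  spec <- cohort_spec(n_subjects = 30, seed = 72,
                      regimen = regimen(75, 12, 1e-7, n_doses = 30,
                                        loading_dose = 150),
                      first_obs_time = 240)  # deep steady state
  co <- simulate_tdm(spec, p0)
  pairs <- cohort_auc_pairs(co, p0)
  expect_equal(pairs$auc_two_point, pairs$auc_model, tolerance = 1e-5)
  agr <- auc_agreement(pairs)
  # absolute bias bound limited by the double-precision representation of
  # the near-bolus peak sampling time (240 h + t_inf)
  expect_equal(agr$bland_altman$mean_bias, 0, tolerance = 1e-4)
  expect_equal(agr$kappa$kappa, 1)
})

test_that("agreement between the AUC methods degrades with residual noise", {
  # near-bolus regimen so the deterministic infusion bias does not mask the
  # noise effect; the same seed gives common random numbers across levels
  kappa_at <- function(sp, sa) {
    p <- pk_params(sigma_prop = sp, sigma_add = sa)
    co <- simulate_tdm(cohort_spec(
      n_subjects = 400, seed = 73,
      regimen = regimen(75, 12, 1e-6, n_doses = 5, loading_dose = 150)), p)
    pairs <- cohort_auc_pairs(co, p)
    auc_agreement(pairs)$kappa$kappa
  }
  k_low <- kappa_at(0.05, 0.02)
  k_mid <- kappa_at(0.30, 0.21)
  k_high <- kappa_at(0.60, 0.8)
  expect_gt(k_low, k_mid)
  expect_gt(k_mid, k_high)
})

test_that("auc_agreement drops incomplete pairs with a count", {
  pairs <- data.frame(auc_two_point = c(60, NA, 120, 80),
                      auc_model = c(55, 70, NA, 85))
  agr <- auc_agreement(pairs)
  expect_equal(agr$n_pairs, 2)
  expect_equal(agr$n_dropped, 2)
})
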