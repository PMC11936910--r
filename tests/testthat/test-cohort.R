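test_that("covariate sampling hits the calibration targets", {
  spec <- cohort_spec(n_subjects = 10000, seed = 42)
  cov <- sample_covariates(spec)
  expect_equal(median(cov$CRCL), 75.99, tolerance = 0.05)
  expect_equal(median(cov$PLT), 163.5, tolerance = 0.05)
  q <- quantile(cov$CRCL, c(0.25, 0.75))
  expect_equal(unname(q[1]), 38.46, tolerance = 0.10)
  expect_equal(unname(q[2]), 130.58, tolerance = 0.10)
  expect_true(all(cov$CRCL > 0) && all(cov$PLT > 0) && all(cov$WT > 0))
  expect_true(abs(mean(cov$SEX) - 0.75) < 0.03)
})

test_that("degenerate covariate spec collapses to the median; fixed seeds reproduce", {
  spec <- fixed_cov_spec(50, seed = 7)
  cov <- sample_covariates(spec)
  expect_true(all(cov$CRCL == 75.99))
  expect_true(all(cov$PLT == 163.5))
  co1 <- make_cohort(25, seed = 9)
  co2 <- make_cohort(25, seed = 9)
  expect_identical(co1$data, co2$data)
  expect_identical(co1$obs, co2$obs)
  co3 <- make_cohort(25, seed = 10)
  expect_false(identical(co1$obs$DV, co3$obs$DV))
})

test_that("noise-free simulation equals the deterministic profile", {
  p0 <- quiet_params()
  co <- simulate_tdm(fixed_cov_spec(5, seed = 1), p0)
  ind <- individual_pk(p0, 75.99, 163.5)
  expect_equal(co$obs$DV, co$obs$TRUE_C, tolerance = 1e-12)
  manual <- vapply(co$obs$TIME, function(tt)
    conc_superposition(ind, co$regimen, tt), numeric(1))
  expect_equal(co$obs$DV, manual, tolerance = 1e-12)
  expect_true(all(co$obs$DV[co$obs$TYPE == "peak"] >
                  co$obs$DV[co$obs$TYPE == "trough"]))
})

test_that("sampling design: trough precedes the 48-h dose, peak ends its infusion", {
  co <- make_cohort(3, seed = 2)
  expect_equal(sort(unique(co$obs$TIME)), c(48, 49))
  expect_equal(unique(co$obs$TIME[co$obs$TYPE == "trough"]), 48)
  expect_equal(unique(co$obs$TIME[co$obs$TYPE == "peak"]), 49)
  d1 <- co$data[co$data$ID == 1, ]
  expect_equal(d1$TIME[d1$EVID == 1], c(0, 12, 24, 36, 48, 60))
  # pre-dose trough is ordered before the simultaneous dose record
  at48 <- d1[d1$TIME == 48, ]
  expect_equal(at48$EVID, c(0L, 1L))
  # trough excludes the concurrent dose: true trough equals 4-dose superposition
  ind <- list(cl = co$subjects$cl[1], v = co$subjects$v[1])
  reg4 <- regimen(75, 12, 1, n_doses = 4, loading_dose = 150)
  expect_equal(co$obs$TRUE_C[co$obs$ID == 1 & co$obs$TYPE == "trough"],
               conc_superposition(ind, reg4, 48), tolerance = 1e-12)
})

test_that("generated cohort recovers the generative IIV and typical peak", {
  co <- make_cohort(500, seed = 3)
  typ_cl <- individual_clearance(ref_params, co$subjects$CRCL, co$subjects$PLT)
  expect_equal(sd(log(co$subjects$cl / typ_cl)), 0.385, tolerance = 0.10)
  # median simulated peak near the noise-free steady-state value 5.31
  co_fix <- simulate_tdm(fixed_cov_spec(400, seed = 4), ref_params)
  med_peak <- median(co_fix$obs$DV[co_fix$obs$TYPE == "peak"])
  expect_equal(med_peak, 5.31, tolerance = 0.10)
})

test_that("NONMEM-style table has the documented schema and consistent records", {
  co <- make_cohort(8, seed = 5)
  expect_identical(names(co$data),
                   c("ID", "TIME", "AMT", "RATE", "DV", "EVID", "MDV",
                     "CRCL", "PLT", "WT", "AGE", "SEX", "OCC"))
  d <- co$data
  expect_true(all(d$MDV[d$EVID == 0] == 0))
  expect_true(all(is.na(d$DV[d$EVID == 1])))
  expect_true(all(d$RATE[d$EVID == 1] == d$AMT[d$EVID == 1] / 1))
  expect_true(all(d$AMT[d$EVID == 0] == 0))
  # loading dose is the first administration, twice maintenance by default
  first_dose <- d[d$EVID == 1 & d$TIME == 0, "AMT"]
  expect_true(all(first_dose == 150))
})

test_that("negative draws are truncated and flagged, LLOQ flagged not dropped", {
  noisy <- pk_params(sigma_prop = 0.1, sigma_add = 3)  # large additive noise
  co <- simulate_tdm(cohort_spec(n_subjects = 200, seed = 6), noisy)
  expect_true(any(co$obs$FLAG == "truncated"))
  expect_true(all(co$obs$DV >= 0))
  expect_equal(nrow(co$obs), 2 * 200)  # nothing dropped
  expect_true(all(co$obs$DV[co$obs$FLAG == "truncated"] == 0))
})

test_that("sampling error of recovered moments shrinks at the 1/sqrt(n) rate", {
  med_spread <- function(n) {
    meds <- vapply(1:40, function(s)
      median(sample_covariates(cohort_spec(n_subjects = n, seed = 1000 + s))$CRCL),
      numeric(1))
    sd(meds)
  }
  s100 <- med_spread(100)
  s400 <- med_spread(400)
  expect_gt(s100 / s400, 1.4)  # ideal ratio 2
  expect_lt(s100 / s400, 2.9)
})

test_that("Cockcroft-Gault matches hand arithmetic and validates age", {
  expect_equal(cockcroft_gault(40, 72, 88.4, "male"), 100, tolerance = 1e-12)
  expect_equal(cockcroft_gault(40, 72, 88.4, "female"), 85, tolerance = 1e-12)
  # ((140-60)*63) / (72 * 79.7/88.4) = 77.64115
  expect_equal(cockcroft_gault(60, 63, 79.7, "male"), 77.64115, tolerance = 1e-6)
  expect_error(cockcroft_gault(140, 70, 88.4, "male"), "140")
})

test_that("total polymyxin concentration combines components on a molar basis", {
  expect_equal(pmb_total_concentration(5, 0, mw1 = 1200, mw2 = 1100,
                                       mw_total = 1200), 5)
  expect_equal(pmb_total_concentration(1, 1, mw1 = 900, mw2 = 900,
                                       mw_total = 900), 2)
  expect_equal(pmb_total_concentration(2, 1, mw1 = 1000, mw2 = 500,
                                       mw_total = 900), 3.6)
})
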