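# shared fixtures: parameter sets and small synthetic cohorts built in code

ref_params <- pmb_reference_params()

# parameter set with selected sources of variability switched off
quiet_params <- function(omega_cl = 0, omega_v = 0, sigma_prop = 0,
                         sigma_add = 0, ...) {
  pk_params(omega_cl = omega_cl, omega_v = omega_v, sigma_prop = sigma_prop,
            sigma_add = sigma_add, ...)
}

make_cohort <- function(n, seed, params = ref_params, ...) {
  simulate_tdm(cohort_spec(n_subjects = n, seed = seed, ...), params)
}

# degenerate covariate distributions: every subject at the median
fixed_cov_spec <- function(n, seed, ...) {
  cohort_spec(n_subjects = n, seed = seed,
              crcl = list(median = 75.99, q1 = 75.99, q3 = 75.99),
              plt = list(median = 163.5, q1 = 163.5, q3 = 163.5),
              weight = list(median = 63, q1 = 63, q3 = 63), ...)
}
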