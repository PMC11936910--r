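# pmbpk

Population pharmacokinetics and dosing simulation for polymyxin B in
critically ill patients, built around steady-state trough/peak (two-point)
therapeutic drug monitoring.

Polymyxin B is a last-line antibiotic against carbapenem-resistant
organisms. Its efficacy target is an exposure ratio, AUC<sub>ss,24h</sub>/MIC ≥ 66.9,
and its safety constraint a therapeutic window of AUC<sub>ss,24h</sub>
50–100 mg·h·L⁻¹ — yet in intensive care it is typically monitored with just
two blood samples per patient: a trough immediately before an infusion at
steady state and a peak at the end of that infusion. This package
implements, tests and connects every quantitative step of that workflow,
for pharmacometricians and clinical-pharmacology researchers:

* **PK core** — closed-form one-compartment intermittent-infusion
  kinetics with the covariate power model on clearance,

  CL = θ_CL · (CrCL/CrCL_med)^θ_CrCL · (PLT/PLT_med)^θ_PLT · e^η,  V = θ_V,

  with exponential inter-individual variability η ~ N(0, ω²) and combined
  proportional + additive residual error (`individual_clearance()`,
  `conc_ss()`, `conc_superposition()`, `auc_model()`). The packaged
  reference estimates for critically ill adults are θ_CL = 2.03 L/h,
  θ_V = 18 L, exponents 0.26 (CrCL) and −0.14 (platelets), ω = 0.385,
  σ_prop = 0.30, σ_add = 0.21 mg/L (`pmb_reference_params()`).
* **Two-point AUC** — the guideline estimator
  k_e = ln(C_peak/C_trough)/(τ − t_inf), C'_soi = C_peak·e^(−k_e·t_inf),
  AUC = (C'_soi − C_trough)/k_e × n (`auc_two_point()`).
* **Synthetic cohorts** — virtual ICU studies with log-normal CrCL/platelet
  distributions calibrated to the reference population, q12h 1-h infusions
  with a loading dose, and paired trough/peak sampling after 48 h
  (`cohort_spec()`, `simulate_tdm()`).
* **Estimation** — Laplace-approximation nonlinear mixed-effects fitting
  with adaptive Gauss-Hermite cross-checks, stepwise covariate selection
  (ΔOFV > 3.84 forward / > 6.63 backward) and nonparametric bootstrap
  (`fit_poppk()`, `covariate_search()`, `bootstrap_poppk()`).
* **Qualification** — visual predictive checks, normalized prediction
  distribution errors with t/variance/Shapiro-Wilk/global tests, and
  external-validation metrics MPE/MAPE/F20/F30 with their acceptance
  thresholds (`vpc()`, `npde()`, `external_validation()`).
* **Dosing simulation** — Monte Carlo probability of target attainment and
  therapeutic-window coverage over the dose × CrCL × platelet grid, with a
  closed-form log-normal oracle for every cell (`run_grid()`,
  `simulate_scenario()`, `window_probs_analytic()`).
* **Agreement** — Bland-Altman, Cohen's κ and McNemar statistics comparing
  the two-point and model-based AUC routes (`auc_agreement()`).
* **Replay** — `replay_study()` runs the whole pipeline end to end on
  synthetic data, reproducibly from one seed.

## Worked example

Simulate an 80-patient cohort from the reference parameters, refit it,
simulate the dosing grid and compare the two AUC methods:

```r
library(pmbpk)
p <- pmb_reference_params()

individual_clearance(p, 75.99, 163.5)      # 2.03 L/h at the covariate medians
ind <- individual_pk(p, 75.99, 163.5)
conc_ss(ind, regimen(75, 12, 1), t = 1)    # 5.31 mg/L end-of-infusion peak
auc_two_point(5.73, 1.69, 12, 1)           # 61.9 mg.h/L from a trough/peak pair

co  <- simulate_tdm(cohort_spec(n_subjects = 80, seed = 7), p)
fit <- fit_poppk(co$data, model_spec(), p)
fit
#> Population PK fit: 80 subjects, 160 observations, OFV 551.723 (converged)
#>               Estimate  RSE%
#> theta_cl      2.061000   4.8
#> theta_v      18.280000   5.4
#> beta_CRCL_cl  0.239200  24.3
#> beta_PLT_cl  -0.005515 980.7
#> omega_cl      0.352500  12.0
#> sigma_prop    0.304800   9.3
#> sigma_add     0.168400  49.6

run_grid(p, n = 1000, seed = 7)$by_dose
#>   dose mean_p_window min_pta
#> 1   50         42.52    61.6
#> 2   75         58.82    89.4
#> 3  100         46.73    97.8
#> 4  125         30.97    99.6

auc_agreement(cohort_auc_pairs(co, as_pk_params(fit)))
#> AUC agreement, two-point vs model-based (79 pairs, 1 dropped)
#> Bland-Altman (n = 79): bias -14.04, SD 7.90, limits [-29.51, 1.44], 92.4% within
#> Cohen's kappa on window classification: 0.508
```

Reading the numbers: the refit recovers the generating fixed effects
(typical clearance 2.06 vs 2.03 L/h; the platelet exponent is weakly
identified at n = 80, exactly why stepwise selection exists), the per-dose
within-window percentages land closest to the 50–100 mg·h·L⁻¹ window for
75 mg q12h, the minimum probability of target attainment at MIC 0.5 mg/L
stays near or above 90% for the 75–125 mg regimens, and on one noisy
trough/peak pair per patient the two AUC routes agree moderately
(κ ≈ 0.5) with a systematic offset — the finite-infusion bias of the
two-point formula that the agreement module is designed to expose. One of
80 pairs was excluded as non-physical (noise made its peak not exceed its
trough), which the table records rather than imputes.

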