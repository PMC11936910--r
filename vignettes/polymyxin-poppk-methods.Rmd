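---
title: "Methods: population pharmacokinetics and dosing simulation for polymyxin B"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacokinetics and dosing simulation for polymyxin B}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmbpk)
```

## The problem

Polymyxin B is a last-line antibiotic against carbapenem-resistant organisms.
Its exposure target is expressed as the 24-hour steady-state area under the
concentration-time curve: efficacy requires AUC~ss,24h~/MIC ≥ 66.9, while
nephrotoxicity risk motivates a therapeutic window of 50–100 mg·h·L^-1^.
Routine monitoring in intensive care relies on two blood samples per patient:
a trough drawn immediately before an infusion at steady state and a peak
drawn at the end of that infusion. `pmbpk` implements the full quantitative
workflow that connects those two samples to dose individualisation: a
population pharmacokinetic (PopPK) model, an estimation engine, model
qualification diagnostics, a Monte Carlo dosing simulator, the guideline
two-point AUC estimator, and agreement statistics between the two AUC
routes — all exercised end to end on synthetic cohorts that the package
generates itself.

## Structural and statistical model

The structural model is a one-compartment disposition with zero-order
(infusion) input and first-order elimination. For subject $i$,

$$CL_i = \theta_{CL}\left(\frac{CrCL_i}{CrCL_{med}}\right)^{\theta_{CrCL}}
\left(\frac{PLT_i}{PLT_{med}}\right)^{\theta_{PLT}} e^{\eta_i},
\qquad \eta_i \sim N(0, \omega_{CL}^2), \qquad V_i = \theta_V,$$

with creatinine clearance (mL/min) and platelet count (10^9^/L) centred at
their population medians. Observed concentrations follow a combined residual
model $y_{ij} = f_{ij}(1 + \varepsilon_{1ij}) + \varepsilon_{2ij}$ with
independent normal proportional and additive terms.

The packaged default parameter set (`pmb_reference_params()`) carries the
published final-model estimates for critically ill adults: $\theta_{CL}$ =
2.03 L/h, $\theta_V$ = 18 L, CrCL exponent 0.26, platelet exponent −0.14,
38.5% inter-individual variability (IIV) on clearance, proportional residual
SD 0.30 and additive residual SD 0.21 mg/L, with medians CrCL 75.99 mL/min
and PLT 163.5·10^9^/L.

Two reporting conventions deserve an explicit statement because published
tables rarely spell them out:

* **IIV scale.** A reported "η~CL~ 38.5%" is interpreted as the log-scale SD
  0.385 of the exponential IIV model — the standard %CV-style convention for
  exponential random effects. This choice is testable: with
  $\omega = 0.385$ the closed-form log-normal exposure distribution
  reproduces the published dosing-grid proportions to within a couple of
  percentage points, whereas reading 0.385 as a variance does not.
* **Residual scale.** The proportional (0.30) and additive (0.21 mg/L)
  residual terms are treated as SDs, consistent with the magnitude of
  plasma concentrations in the 1–8 mg/L range.

All concentration formulas use the closed-form intermittent-infusion
solutions (`conc_ss()`, `conc_superposition()`), written with `expm1()` so
that the bolus limit $t_{inf} \to 0$ is exact to machine precision — a
property the two-point estimator tests rely on.

## The two-point AUC estimator

The guideline estimator (`auc_two_point()`) assumes a mono-exponential
decline between peak and trough:

$$k_e = \frac{\ln C_{peak} - \ln C_{trough}}{\tau - t_{inf}}, \qquad
C_{soi}' = C_{peak} e^{-k_e t_{inf}}, \qquad
AUC_{ss,24h} = \frac{C_{soi}' - C_{trough}}{k_e}\, n,$$

with $n$ doses per 24 h. The interval area is treated literally as an
exponential fall from the back-extrapolated start-of-interval concentration
to the trough; the infusion-phase area is not modelled separately. In the
bolus limit this is exact for linear one-compartment kinetics (equal to
daily dose / CL to 10^-9^ relative, which the tests assert); for a 1-hour
infusion it carries a small deterministic bias that depends only on
$k_e\tau$ and $k_e t_{inf}$ — the package characterises this bias rather
than hiding it, because it is precisely what the agreement analysis between
the two AUC methods measures. Pairs that are non-physical under residual
noise (peak ≤ trough) are excluded with a logged reason and counted, never
imputed.

## Synthetic cohorts: what they emulate and what they do not

`simulate_tdm()` generates virtual studies with the structure the analysis
assumes:

* independent log-normal CrCL and PLT calibrated to the reported
  median/IQR of the modelled population (median 75.99, IQR 38.46–130.58
  mL/min; median 163.5, IQR 84.5–266.25 ·10^9^/L) via
  `sdlog = (ln q3 − ln q1)/(2 × 0.6745)`. The source reports only
  marginals, so the default inter-covariate correlation is zero;
* a q12h regimen with a 1-hour infusion and, by default, a loading dose of
  twice the maintenance dose (nearly all patients in the source population
  received a loading dose; the multiple is a configurable convention since
  only mg/kg summaries are published);
* paired trough/peak sampling in the first dosing interval at or after 48 h
  of treatment, the trough drawn immediately before the concurrent dose (so
  its prediction excludes that dose) and the peak at the end of the
  infusion;
* combined proportional + additive residual noise, with negative draws
  truncated at zero and flagged, and observations below the 0.2 mg/L assay
  quantification limit flagged but retained.

The generator deliberately does **not** emulate: time-varying covariates
within a subject, renal replacement or ECMO, correlated covariates,
inter-occasion variability, or irregular real-world sampling times. Passing
tests on these cohorts therefore demonstrate that the estimation and
diagnostic machinery is correct under the model's own assumptions; they do
not demonstrate robustness to the violations that real intensive-care data
would bring.

## Estimation engine

`fit_poppk()` maximises an approximate marginal likelihood. Each subject's
random effect is integrated by a **Laplace expansion about the empirical
Bayes mode**, with the residual variance evaluated at the individual
predictions — the closest well-defined analogue of conditional estimation
with interaction when the reference implementation's internals are not
published. The inner problem (per-subject modes) is solved by a vectorised
safeguarded Newton iteration with numerical derivatives (gradient tolerance
10^-6^); the outer problem runs Nelder-Mead on log-transformed parameters
(positivity by construction; covariate exponents unconstrained), with one
fresh-simplex restart from the incumbent because a collapsed simplex is the
one failure mode we observed in replicate studies. Standard errors come
from the numerically differentiated Hessian of the objective with a delta
back-transformation; a non-positive-definite Hessian flags the standard
errors as unavailable instead of failing the fit.

An **adaptive Gauss-Hermite** alternative (`method = "agq"`, 64 nodes in the
oracle checks) integrates the same joint density to near machine precision;
on a single subject it agrees with `stats::integrate` to seven decimals.
The two routes are kept deliberately distinct: the quadrature is the
correctness oracle for the Laplace code path, never its replacement. One
finding from that comparison is worth recording: with only two observations
per subject and 30% proportional error, the *genuine* Laplace approximation
error is about 0.05–0.1 OFV units per subject (the integrand over $\eta$ is
visibly skewed), so Laplace and 64-node quadrature differ by a few units on
a 50-subject set. This is a property of the approximation, not a defect of
the implementation; the test suite documents it.

Covariate selection (`covariate_search()`) follows the conventional
stepwise procedure: greedy forward addition accepting the best candidate
when the objective drops by more than 3.84 (χ², df 1, p < 0.05), then
backward elimination removing any covariate whose deletion raises the
objective by at most 6.63 (p < 0.01). Ties are broken by candidate order.
The nonparametric bootstrap (`bootstrap_poppk()`) resamples subjects with
replacement, refits each replicate warm-started at the original estimates,
and reports medians with 2.5–97.5 percentile intervals; failed replicates
are counted and more than 20% failures raises a warning.

Numerical choices, stated once: parameters are estimated as log-SDs/log
values with exponents free; the inner Newton uses central differences with
step 10^-3^; the degenerate case $\omega \to 0$ switches analytically to
the fixed-effects weighted least-squares deviance; residual variances are
floored at 10^-12^ to keep noise-free degenerate inputs finite.

## Model qualification

* `external_validation()` computes MPE%, MAPE%, and the fractions F20/F30 of
  predictions within 20%/30% of the observation, with inclusive boundaries
  (so a uniform +20% prediction error yields F20 = 100%), and enforces the
  published acceptance thresholds MPE% ≤ ±20%, MAPE% ≤ 30%, F20 ≥ 35%,
  F30 ≥ 50%.
* `vpc()` overlays observed percentiles (5/50/95 by default) on the
  confidence bands of the same percentiles across simulation replicates,
  binned by nominal sampling time (trough and peak bins in the reference
  design).
* `npde()` decorrelates each subject's observed vector with the empirical
  mean and Cholesky factor of its simulated counterparts, maps the rank of
  the decorrelated observation among the decorrelated simulations through
  $\Phi^{-1}$ (using the $(r + 0.5)/(K + 1)$ mid-rank convention to avoid
  infinite scores), and reports four tests: t-test of mean zero, two-sided
  χ² ("Fisher") test of variance one, Shapiro-Wilk normality, and a
  Bonferroni combination of the three as the global test — the standard
  construction where a "global test" is named without definition. A
  singular simulated covariance is ridge-regularised with a warning.

## Dosing simulator

Because steady-state AUC equals daily dose / CL for linear kinetics,
neither the infusion profile nor the loading dose enters the simulated
exposure; `simulate_scenario()` draws clearances
$CL_i = CL_{typ}(CrCL, PLT)\, e^{\eta_i}$ at fixed scenario covariates
(representative values are compared, not sampled) and classifies
$AUC_i$ = daily dose / $CL_i$ against the 50–100 mg·h·L^-1^ window
(boundaries inclusive — a probability-zero event for continuous clearance)
and the AUC/MIC ≥ 66.9 target. The exposure distribution is exactly
log-normal, so every cell probability has a closed form
(`window_probs_analytic()`, `pta_analytic()`) that serves as the analytic
oracle for the Monte Carlo engine: at 1000 subjects per cell the simulated
and exact proportions agree within binomial noise (≤ 3.2 points, ~2 SD),
and at 2×10^5^ subjects within 0.5 points. The default grid reproduces the
published design: doses 50/75/100/125 mg q12h, CrCL 30–150 mL/min in steps
of 30, platelets at the population quartiles 85 and 266·10^9^/L, 1000
subjects per cell, with per-cell derived seeds so any single cell can be
reproduced in isolation.

A reference copy of the published grid ships as plain text
(`reference_grid()`). Recomputing the per-dose mean within-window
percentages from those printed cells gives 42.41 / 58.13 / 46.78 / 30.88
for 50/75/100/125 mg; the first three match the published summary figures
(42.40/58.13/46.78), while the published 125-mg summary of 14.66% is
inconsistent with its own table — the package treats the printed cells as
authoritative, and the model's exact mean (31.08%) supports that choice.

## Agreement between the AUC methods

`auc_agreement()` compares two-point and model-based AUC subject by
subject: Bland-Altman mean bias with limits of agreement (mean ± 1.96 SD —
the construction the usual "95% interval of the differences" description
matches), Cohen's κ on the inside/outside-window dichotomy (below- and
above-window pooled as "outside"), and McNemar's test, continuity-corrected
by default with an exact binomial form when there are fewer than 25
discordant pairs (the reference analysis does not state which form it
used; both are available). With noise off and a near-bolus infusion the
two methods agree exactly (bias 0, κ = 1), and agreement degrades
monotonically as residual noise grows — the qualitative pattern the
moderate published κ illustrates on real data.

## Problem sizes used in the shipped studies

The test-suite experiments are sized for reproducible laptop-scale runs and
state their own conditions: parameter recovery uses 200 subjects with two
samples each (the study's sampling design); the null-covariate ΔOFV
calibration uses 500 replicates of 50 subjects (large enough for the
chi-square asymptotics of the likelihood-ratio statistic to hold) with the
volume and residual parameters held at their generating values in the
nuisance dimension; NPDE type-I calibration uses 200 replicates of 50 subjects with
200 simulations each; the dosing grid uses the published 1000 subjects per
cell, with 2×10^5^-subject runs only where the simulator is compared with
its analytic oracle. `replay_study()` defaults mirror the source design (80
modelling + 15 validation subjects) with reduced bootstrap and simulation
counts, all adjustable.

## Known limitations

* Single random effect on clearance in the default model; the
  two-random-effect (CL, V) path exists but uses a slower per-subject 2-D
  Laplace and is intended for base-model exploration, not production fits.
* No inter-occasion variability, SAEM-type estimation, or η covariance.
* The two-point estimator accepts nominal sampling times by default;
  actual-time columns are supported but deviations are not simulated.
* Laplace-vs-quadrature disagreement of a few OFV units per 50 subjects is
  inherent to the two-sample design and 30% proportional noise (see above);
  inference that depends on absolute OFV differences across *methods*
  should use a single method throughout, as `covariate_search()` does.
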