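Package: pmbpk
Title: Population Pharmacokinetics and Dosing Simulation for Polymyxin B
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population pharmacokinetic analysis of polymyxin B in
    critically ill patients from steady-state trough and peak concentrations.
    Implements the closed-form one-compartment intermittent-infusion model with
    a power covariate model for clearance (creatinine clearance and platelet
    count), a Laplace-approximation nonlinear mixed-effects estimation engine
    with stepwise covariate selection and nonparametric bootstrap, model
    qualification diagnostics (visual predictive checks, normalized prediction
    distribution errors, external-validation metrics), Monte Carlo dosing
    simulation of probability of target attainment and therapeutic-window
    coverage over dose by renal-function grids, the guideline two-point
    trough/peak AUC estimator, and Bland-Altman / kappa / McNemar agreement
    statistics between AUC estimation methods. A synthetic-cohort generator
    emulating the covariate and sampling structure of intensive-care polymyxin
    B therapy makes the whole workflow reproducible without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    withr
Config/testthat/edition: 3
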