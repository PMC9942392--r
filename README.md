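# mfpcsurv

Dynamic prediction of overall survival after curative colorectal-cancer
surgery from sparse, irregularly sampled perioperative serum tumor
markers (CEA, CA19-9, CA125), for biostatisticians and clinical
researchers who want postoperative marker series — not just the
preoperative value — to drive a prognostic model.

## The method

Each marker's log-scale trajectory is decomposed by sparse functional
principal component analysis (PACE):

    Y_ij = mu(t_ij) + sum_k  xi_ik  phi_k(t_ij) + eps_ij,

with the smooth mean `mu`, orthonormal eigenfunctions `phi_k`
(eigenvalues `lambda_1 >= ... >= lambda_K`), per-patient scores `xi_ik`
estimated as best linear unbiased predictors from the patient's own few
noisy observations, and the number of components chosen by AIC. Values
are truncated at ten times the marker's reference upper limit (CEA
5 ng/ml, CA19-9 37 U/ml, CA125 35 U/ml) before the log.

The three markers' scores are stacked and a multivariate FPCA
(eigendecomposition of the stacked score covariance) yields joint
trajectory features. A random survival forest (log-rank splits,
Nelson–Aalen leaves) maps features to survival curves; model
configurations range from covariates-only (`basic`) through preoperative
marker models to `longitudinal_3marker` (covariates + preoperative
values + joint trajectory scores). Prediction is anchored at the
landmark `s = 12` months: conditional survival is

    pi(s' | s) = S(s') / S(s),

updated by re-estimating the FPC scores whenever a new measurement
arrives within the 12-month feature horizon. Configurations are compared
with IPCW time-dependent AUC and Brier score, category-free NRI, and
IDI, under tenfold cross-validation; a synthetic-cohort generator with
known ground truth (trajectory eigenstructure, true event and censoring
times, score-driven Weibull hazard) makes every stage testable.

## Worked example

```r
library(mfpcsurv)

## a synthetic cohort: 300 patients, three correlated markers,
## hazard driven by the leading trajectory score of each marker + stage
cohort <- generate_cohort(cohort_config(n_patients = 300, seed = 7))

ctrl <- fpca_control(grid_len = 51, bw_mean = 1, bw_cov = 2.5)
pl <- fit_pipeline(cohort$measurements, cohort$patients,
                   configuration = "longitudinal_3marker",
                   control = ctrl, num_trees = 300, seed = 3)
pl$fpca[["CEA"]]
#> Sparse FPCA model (CEA)
#>   K = 2  eigenvalues: 3.609, 1.175
#>   sigma2 = 0.1775  bandwidths: 1 / 2.5

## compare configurations by cross-validated IPCW AUC / Brier score
cv <- cross_validate(cohort$measurements, cohort$patients,
                     configurations = c("basic", "preop_3marker",
                                        "longitudinal_3marker"),
                     folds = 5, horizons = c(24, 36, 48),
                     control = ctrl, num_trees = 200, seed = 11)
cv$metrics
#>          configuration landmark horizon   auc  brier n_events n_at_risk
#> 1                basic       12      24 0.392 0.1173       31       204
#> 2                basic       12      36 0.477 0.2022       63       167
#> 3                basic       12      48 0.495 0.2263       76       147
#> 4        preop_3marker       12      24 0.745 0.0989       31       204
#> 5        preop_3marker       12      36 0.719 0.1732       63       167
#> 6        preop_3marker       12      48 0.726 0.1909       76       147
#> 7 longitudinal_3marker       12      24 0.828 0.0793       31       204
#> 8 longitudinal_3marker       12      36 0.783 0.1533       63       167
#> 9 longitudinal_3marker       12      48 0.811 0.1605       76       147

## dynamic prediction for one patient, updated with a new measurement
pat <- cohort$patients[1, ]
hist <- cohort$measurements[cohort$measurements$patient_id ==
                              pat$patient_id, ]
predict_patient(pl, pat, hist, horizons = c(24, 36, 48, 60))$pi
#>      24    36    48    60
#> 1 0.691 0.412 0.239 0.184
update_with_measurement(pl, pat, hist,
                        list(marker = "CEA", time_months = 11.5,
                             value = 40),
                        horizons = c(24, 36, 48, 60))$pi
#>      24    36    48   60
#> 1 0.521 0.299 0.191 0.16
```

The FPCA print shows the selected number of components, the estimated
eigenvalues (log-scale variances; the generator's truth is 4 and 1) and
the measurement-error variance. In the cross-validation table the
longitudinal configuration attains the highest AUC and lowest Brier
score at every horizon, the preoperative configuration sits in between,
and covariates alone do worst — the ordering the method is built to
demonstrate. In the dynamic-prediction output, appending a high CEA
value (40 ng/ml at 11.5 months, against a falling fitted trajectory)
re-estimates the patient's scores and lowers the conditional survival
curve.

## Layout

- `R/` — generator, preprocessing, sparse FPCA, MFPCA, survival forest,
  dynamic prediction, evaluation metrics, workflow orchestration
- `src/` — local-linear kernel smoothers (Rcpp)
- `tests/testthat/` — unit, property and acceptance tests with
  brute-force oracles
- `vignettes/dynamic-marker-prognosis.Rmd` — the methods vignette
- `scripts/acceptance.R` — the reproduction script
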