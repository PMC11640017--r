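# hazardnet

Discrete-time deep survival analysis with time-varying covariates, for
longitudinal claims-style oncology cohorts.

## The problem

For patients with stage IV breast cancer, survival varies enormously with
circumstances that accumulate *after* diagnosis — treatments received,
adverse events experienced, evolving comorbidity. Classical survival
models built from diagnosis-time ("time-fixed") covariates alone summarise
the population but discriminate poorly between individual patients. This
package implements, end to end, the experiment showing that **extending
each patient's covariate vector with summaries of their visit history
sharply improves individual survival prediction**, across four
neural-network survival objectives.

Because the claims data motivating this design are restricted, the package
ships a **synthetic cohort generator** that emulates their structure on a
monthly grid — truncated-normal age (mean 76.0, floor 65), overdispersed
comorbidity (mean 1.6, SD 2.6), a visit process with a state-dependent
treatment policy, 18 adverse-event categories drawn conditionally on
treatment, and administrative right-censoring — and generates death from a
known logistic discrete hazard

$$h(t \mid x) = \mathrm{logit}^{-1}\!\big(\mathrm{logit}(h_0) +
\beta_f^\top x_{\text{fixed}} + \beta_v^\top s(t)\big),
\qquad S(t \mid x) = \prod_{s \le t} \big(1 - h(s \mid x)\big),$$

where $s(t)$ summarises the history up to month $t$. Ground truth travels
with every cohort, so parameter recovery and direction-of-effect claims
are testable.

## What is implemented

| Layer | Functions |
|---|---|
| Synthetic cohort | `generator_config`, `generate_cohort`, `true_survival_curve`, `cohort_summary`, `write_cohort`/`read_cohort` |
| Timeline preparation | `clean_records`, `bucket_continuous`, `extend_covariates`, `encode_dataset`, `standardize_dataset`, `default_code_maps` |
| Survival objectives | `loss_deepsurv` (Cox partial likelihood, Breslow ties), `loss_logistic_hazard` (Nnet-survival), `loss_deephit` (likelihood + ranking), `loss_cox_time` (sampled risk sets); `fit`, `predict_survival`, `save_model`/`load_model` |
| Metrics | `km_estimator`, `ctd_index` (Antolini time-dependent concordance), `brier_score` / `integrated_brier_score` (Graf, IPCW), `summarize_folds` |
| Experiments | `crossvalidate` (patient-level folds), `tune` (random / simple model-based search over the published space), `compare_covariate_sets`, `predict_patient_curves` |

The networks (fully connected, ReLU, dropout, Adam, analytic gradients
per loss) are implemented in-package; every metric and loss is backed by
an independent brute-force oracle in the test suite. See
`vignettes/methods.Rmd` for the models, assumptions, parameter choices
and limitations.

## Worked example: the analysis workflow

The numbered scripts under `analysis/` run the whole study and write
their tables under `results/`:

```sh
Rscript analysis/01_simulate.R           # calibrated synthetic cohort
Rscript analysis/02_prepare.R            # clean + encode both representations
Rscript analysis/03_tune.R               # small random search (optional)
Rscript analysis/04_compare_covariates.R # the central experiment
Rscript analysis/05_patient_curves.R     # individual survival curves
```

Step 1 prints the calibration of the simulated population:

```
cohort: 2000 patients, 42672 visit entries
age at diagnosis: 76.02 +/- 6.36 (target mean 76.0)
baseline comorbidity: 1.63 +/- 2.74 (target mean 1.6)
event fraction: 0.88 (remainder administratively censored)
```

Step 4 cross-validates all four families (five patient-level folds,
desk-scale epochs) under both covariate representations:

```
deepsurv         Ctd fixed 0.551 +/- 0.013 | Ctd extended 0.632 +/- 0.017 | IBS fixed 0.183 +/- 0.003 | IBS extended 0.166 +/- 0.006
deephit          Ctd fixed 0.537 +/- 0.020 | Ctd extended 0.633 +/- 0.011 | IBS fixed 0.185 +/- 0.003 | IBS extended 0.165 +/- 0.003
logistic_hazard  Ctd fixed 0.547 +/- 0.016 | Ctd extended 0.631 +/- 0.015 | IBS fixed 0.187 +/- 0.003 | IBS extended 0.169 +/- 0.007
cox_time         Ctd fixed 0.555 +/- 0.015 | Ctd extended 0.625 +/- 0.012 | IBS fixed 0.184 +/- 0.003 | IBS extended 0.166 +/- 0.006
families with a concordance gain beyond fold noise: 4 of 4
```

Every family gains roughly 0.08–0.10 in time-dependent concordance (and
loses Brier error) from the extended covariates; with the generator's
time-varying coefficients zeroed the gap collapses into fold noise (that
control is exercised in the test suite). Held-out patients are evaluated
at their earliest landmark, so the gain reflects baseline-visit history
only — the honest prediction setting — which is why the absolute numbers
sit well below what in-sample or late-landmark evaluation would give.

Step 5 trains an extended model and predicts curves for five synthetic
profiles spanning low to high risk:

```
      patient_id median_months defined
1       low_risk            81    TRUE
2    modest_risk            54    TRUE
3        average            13    TRUE
4      high_risk             7    TRUE
5 very_high_risk             4    TRUE
median survival spread: 4 to 81 months
```

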