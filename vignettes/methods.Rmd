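---
title: "Discrete-time survival networks with time-varying covariates: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete-time survival networks with time-varying covariates: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Patients with stage IV breast cancer generate long, irregular claims
timelines: monthly visits carrying treatments (chemotherapy, biotherapy,
hormone therapy), adverse events, and an evolving comorbidity index. The
question the package addresses is whether, and by how much, summarising
that accumulated history improves *individual* survival prediction over
using only the covariates known at diagnosis. The linked claims data that
motivate this design are restricted, so the package pairs the modelling
machinery with a synthetic cohort generator that reproduces the structural
features of such data — and, crucially, knows its own ground truth.

# Discrete-time framework

Follow-up is divided into months. We observe $T = \min(T^*, C^*)$, the
earlier of the death time $T^*$ and the administrative censoring time
$C^*$ (the study window closing), and the indicator $D = 1\{T = T^*\}$.
A discrete hazard is the conditional event probability per month,
$h(t \mid x) = P(T^* = t \mid T^* \ge t, x)$, and the survival function is
$S(t \mid x) = \prod_{s \le t}\,(1 - h(s \mid x))$.

Four objectives are implemented on a shared feed-forward network:

* **deepsurv** — Cox partial likelihood with a network risk score $g(x)$:
  $h(t\mid x) = h_0(t)\,e^{g(x)}$. Ties are handled by Breslow's
  convention (every event at a tied time sees the full risk set), and the
  baseline cumulative hazard is recovered post hoc by the Breslow
  estimator. Proportional hazards is assumed.
* **logistic_hazard** (Nnet-survival) — the network emits one logit per
  interval; the loss is the exact Bernoulli likelihood of surviving each
  interval. No proportionality assumption.
* **deephit** — the network emits a probability mass function over
  intervals plus a beyond-horizon remainder via a softmax; the loss mixes
  the likelihood term with a pairwise ranking penalty
  $\exp(-(F_i(T_i) - F_j(T_i))/\sigma)$ weighted by $\alpha$.
* **cox_time** — the score may depend on time, $g(t, x)$; the partial
  likelihood is approximated by sampled risk sets (case plus
  `n_control_samples` controls drawn from subjects still at risk), and
  survival comes from a Breslow-type baseline evaluated with
  time-dependent scores.

The networks themselves are intentionally plain: fully connected layers,
rectified-linear activations, inverted dropout, Adam updates, analytic
gradients for every loss (finite-difference checked in the test suite),
and early stopping on a patient-level validation split. Everything is
deterministic given the configuration seed; child seeds for batching,
dropout, control sampling and fold assignment are fanned out from the
master seed by a mixing function (`derive_seed`), so no two consumers
share a stream.

# Covariate extension

The extended covariate vector at a landmark month concatenates

* the **fixed block**: bucketed age, race code, ER/PR/HER2 status, grade,
  histology code; and
* the **history block**, computed strictly from visits at or before the
  landmark: cumulative counts per treatment class and per adverse-event
  category (18 categories, with totals), the most recent comorbidity
  index (bucketed), months since diagnosis, months since last treatment,
  and an ever-treated indicator.

The no-lookahead property — perturbing any visit after the landmark never
changes the vector — is enforced by construction and verified by a
property test. Where the summary set was an open choice we kept the
simplest representation (cumulative counts plus recency); the set lives
behind one function and is deliberately pluggable.

Two conventions needed fixing and are therefore stated at the interface:
buckets are half-open $[b_i, b_{i+1})$ with values below the first
boundary mapping to bucket 0; and when no treatment has occurred the
months-since-treatment feature equals months-since-diagnosis (its maximal
possible value) with `ever_treated = 0` disambiguating, which keeps every
feature numeric and finite without a magic sentinel.

**Landmarking.** In extended mode the default encoding creates one row
per patient per visit month, with the outcome re-expressed as residual
time from the landmark. This is the standard discrete-time treatment of
time-varying covariates and preserves no-lookahead; a
single-row-at-last-visit policy is available. A landmark in the same
month as death or censoring would leave a zero-length residual with no
interval to put the outcome in, so such rows are dropped (the visit still
feeds the history of nothing — it has no later landmark to feed).
Held-out patients are represented by their *earliest* landmark by default
(one row per patient, full residual follow-up), configurable to all
landmarks.

# The synthetic cohort generator

The generator is the package's study population, not a test fixture: its
defaults define the conditions every experiment runs under.

* **Age**: truncated normal, floor 65 (an age-eligibility population),
  location re-centred numerically so the post-truncation mean hits 76.0
  with nominal SD 7.5. Truncation shrinks the realised SD below 7.5;
  the calibration contract is the mean.
* **Baseline comorbidity**: negative binomial with mean 1.6 and SD 2.6
  (the printed SD exceeds the mean, which forces overdispersion), with a
  monthly random-walk drift upward, accelerated by adverse events.
* **Timeline**: 300 monthly intervals; diagnosis month uniform over the
  window; a guaranteed diagnosis-month visit then Bernoulli(0.6) visits
  per month; administrative censoring for patients alive at the window
  end.
* **Treatment policy**: chemotherapy probability decays exponentially
  from diagnosis (base 0.45, 24-month scale), hormone therapy ramps up
  for receptor-positive patients, biotherapy targets HER2-positive
  patients. This creates informative time-varying structure without any
  claim of clinical realism.
* **Adverse events**: 18 categories with per-category probabilities
  decaying geometrically from 0.12 in treated months, scaled by 0.15 in
  untreated months.
* **Hazard**: logistic discrete hazard, baseline 0.012 per month, fixed
  log-hazard ratios on standardised age (0.30), ER (−0.30), PR (−0.15),
  HER2 (−0.10) and centred grade (0.25), and time-varying log-hazard
  ratios on the latest comorbidity index (0.30), cumulative adverse-event
  burden (0.08) and cumulative chemotherapy months (−0.05). These values
  were chosen once to give a median survival around two to three years, a
  high event fraction under administrative censoring, and a history
  signal that is strong but not degenerate.

Because death is generated from exactly the discrete-hazard family the
models fit, parameter recovery is well-posed and `true_survival_curve`
gives the exact ground-truth curve for any covariate profile and visit
history — the oracle used by the recovery tests.

What the generator does **not** emulate: multiple claims per month,
informative (non-administrative) censoring, measurement error in codes,
treatment choice responding to prognosis (confounding by indication), and
real marginal distributions beyond the two calibrated moments. Passing
tests therefore demonstrate correctness of the machinery and the
direction of the covariate-extension effect under a known
data-generating process, not clinical performance.

# Evaluation

* **Time-dependent concordance** (Antolini): over comparable pairs —
  $i$ an event with $T_i < T_j$, or $T_i = T_j$ with $j$ censored — the
  fraction with $S_i(T_i) < S_j(T_i)$, ties counting one half. It is
  scale-free (invariant to strictly monotone transformations of the
  predictions at each time), 1 for perfect discrimination, 0.5 for
  chance; both endpoints are verified exactly in the tests.
* **Integrated Brier score** (Graf): inverse-probability-of-censoring
  weighted squared error, weights $1/G(T_i^-)$ for events before $t$ and
  $1/G(t)$ for subjects at risk past $t$, $G$ the Kaplan–Meier estimate
  of the censoring distribution; integrated by the trapezoidal rule and
  normalised by the grid span. The default grid stops at the 90th
  percentile of observed durations because $G$ is unstable in the tail;
  rows needing a weight where $G = 0$ are excluded and reported.

Both metrics are implemented directly from their definitions and checked
against exhaustive brute-force oracles (explicit pairwise loops, explicit
weighted sums) on hundreds of random small instances.

# Experiments

`crossvalidate` partitions *patients*, never landmark rows, so no
patient's visits can straddle the train/test boundary; standardisation is
fitted on training rows only. `compare_covariate_sets` runs every family
under both covariate modes and reports fold-wise mean ± SD; the scale we
use for calling a gap real is $\sqrt{\mathrm{sd}_{\text{fixed}}^2 +
\mathrm{sd}_{\text{ext}}^2}$, the standard deviation of a difference of
independently varying fold means. `tune` replaces a managed
cloud search with an in-repo scheme over the same space: pure random
search, or a simple sequential surrogate that, after a random warm-up,
restricts sampling to hyperparameter values seen in the top quartile of
the trace so far. Ties go to the first configuration evaluated.

# Numerical choices

* Probabilities are epsilon-clamped (1e−7) only on the side entering a
  logarithm, so exact-zero contributions stay exact; clamping is
  reported.
* Discrete outputs use a quantile-coarsened interval grid (default at
  most 50 intervals) so the network head stays small; the monthly grid
  remains the data-level truth. Desk-scale experiments in the tests and
  analysis scripts use 8–30 intervals, 20–40 epochs and cohorts of
  600–2,000 patients — sizes chosen so the full suite runs comfortably on
  a single CPU.
* The cox_time baseline subsamples each risk set (cap 512) for its
  denominator; the estimate is unbiased for the risk-set mean and the cap
  only matters for cohorts far above desk scale.
* Zero-variance features standardise to zero with unit scale rather than
  dividing by zero.
* `hazard_model_config(strict = TRUE)` pins every hyperparameter to the
  published tuning sets; plain construction accepts any positive values
  so that reduced-epoch desk runs are expressible. Sampling from the
  search space always satisfies the strict check.

# Known limitations

Single event type (death) only — no competing risks; no learned
embeddings or recurrent encoders over the raw visit sequence (the history
enters through fixed summaries); the ranking term of DeepHit is computed
within mini-batches; confidence intervals for the metrics are not
provided (fold SDs are).
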