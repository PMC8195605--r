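---
title: "Federated causal analysis of medication exposure in claims data: methods"
author: "fedclaims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated causal analysis of medication exposure in claims data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedclaims)
```

## The question and the design

Alpha-1 adrenergic receptor (alpha-1-AR) antagonists — tamsulosin, doxazosin
and relatives, widely prescribed to older men for benign prostatic
hyperplasia — plausibly dampen the catecholamine-driven cytokine amplification
that turns a lower respiratory tract infection into hyperinflammation,
mechanical ventilation and death. `fedclaims` implements a target-trial
emulation of that hypothesis on insurance-claims-shaped data: among older men
hospitalized with acute respiratory distress (ARD) or pneumonia, does prior
regular use of an alpha-1-AR antagonist reduce the odds of mechanical
ventilation, and of ventilation followed by death?

Because the claims warehouses such studies run on are license-restricted,
the package ships a synthetic multi-source claims generator with a known
ground truth, and the entire pipeline — cohort construction, three estimators,
federation and sensitivity analysis — runs end to end against it. Every design
element of the real analysis is preserved: confounding by indication, two
source "dialects" with different death coding, age caps and ICD-era calendar
gaps, and privacy constraints that forbid pooling patient-level records.

## Study definitions

**Exposure.** A patient is *exposed* if the medication possession ratio (MPR)
— days of qualifying drug supplied inside the 365-day pre-index window,
truncated at the index date, divided by 365 — is at least 0.5, i.e. supply
covering six of the last twelve months. A patient with no qualifying fill in
the window is *unexposed*. Patients with 0 < MPR < 0.5 are excluded
outright: partial users are neither clean controls nor plausibly treated.
Overlapping supplies are summed, not merged, so the MPR can exceed 1; we use
it as-is against the threshold, the simplest reading of "possession ratio".

**Index admission.** The first inpatient admission carrying a diagnosis code
in the cohort codeset, restricted to calendar years in which the code era is
usable for that source (e.g. one source contributes 2004–2015 and 2018–2019
but not the ICD-9/ICD-10 transition years). Eligibility further requires
male sex, age 45–85 at index (one source is capped at 65 by construction,
mirroring Medicare exclusion in employer-sponsored claims), and 12 months of
continuous enrollment before index. The enrollment rule is our own
explicit choice: the MPR and every confounder lookback need an observable
prior year, so we require it rather than leave it implicit.

**Outcomes.** Ventilation is a ventilation procedure code on the index stay.
The composite outcome requires ventilation *and* death, where death follows
the source dialect: an in-hospital death flag, or a recorded death month
within one month of the admission month. A death-only variant (for registry
sources where ventilation is unreliably coded) is available via
`outcome_set = "death"`.

**Confounders.** Age, fiscal year, four utilization counts from the prior
year (weeks with inpatient admissions, total inpatient days, outpatient
visits, plus weeks with inpatient admissions in the prior two months) and
seven comorbidity flags (hypertension, ischemic heart disease, acute MI,
heart failure, COPD, diabetes, cancer) from coded encounters in the prior
365 days. Utilization counts are log(1 + x)-transformed — counts are
frequently zero, so a bare log is undefined — and every column is de-meaned
and scaled to unit variance cohort-wide. Fiscal year enters as a continuous
standardized covariate rather than as fixed effects: this keeps the design
matrix identical across small cohorts; it is a modeling choice, not a claim
about the original analysis.

## The three estimators

**Unadjusted.** Fisher's exact test on the 2x2 exposure-by-outcome table:
the conditional maximum-likelihood odds ratio under the noncentral
hypergeometric model, its exact conditional 95% CI, and a one-sided p in the
protective direction (the hypergeometric tail probability of at most the
observed exposed-outcome count). We also report the relative risk reduction
RRR = 1 − p_x/p_y with a first-order delta-method variance,

$$\widehat{Var}(\widehat{RRR}) \;=\; \frac{1}{n_x}\frac{\hat p_x(1-\hat p_x)}{\hat p_y^2}
 \;+\; \frac{1}{n_y}\frac{\hat p_x^2\,\hat p_y(1-\hat p_y)}{\hat p_y^4}.$$

Being first-order, this variance ignores the convexity of $1/\hat p_y$; it
is accurate when the unexposed arm is large (within 2% of a parametric
bootstrap at 1,000 per arm in our tests) but understates the variance
noticeably for arms of ~100 with p_y = 0.2, where cv(p_y) = 0.2. We use the
printed formula as the pooling weight throughout and document the limitation
rather than silently substituting a higher-order expansion.

**Adjusted.** Propensity scores e(x) are estimated nonparametrically by
cross-fitted gradient-boosted trees (`xgboost`; exact greedy splits, depth 3,
learning rate 0.1, 100 rounds, minimum child weight 10, no row subsampling;
a `ranger` probability forest is available behind `method = "ranger"`).
Cross-fitting makes every score out-of-sample. Fold membership is a
deterministic hash of the covariate row rather than the row index, and
training rows are fed to the learner in hash order: scores are therefore
reproducible *and* equivariant under permutation of patients, a property we
test. Scores are clamped to [1e-4, 1 − 1e-4].

Analysis is then restricted to the common-support band — scores between the
larger of the two arms' 1st percentiles and the smaller of their 99th
percentiles (closed interval, type-7 interpolated quantiles) — and the odds
ratio comes from a weighted logistic regression of outcome on exposure and
all confounders. Default weights target the treated population (ATT):
exposed 1, unexposed e/(1−e), which reweights the unexposed arm to resemble
the exposed arm; ATE weights are available but not default. The exposure
coefficient's variance uses the HC0 sandwich estimator, giving Wald CIs and
a one-sided protective p. Including the covariates in the outcome model
makes the estimator doubly robust: valid if either the outcome regression or
the propensity model is correct.

**Matched.** On the trimmed sample, each exposed patient (in a seeded random
order, since greedy matching is order-dependent and no canonical order
exists) receives up to five unexposed matches of *identical integer age*,
without replacement, ranked by Mahalanobis distance on the standardized
non-age confounders. A caliper of 0.2 is applied; "0.2" alone is ambiguous,
and we adopt the conventional reading — 0.2 SD of the logit propensity
score — with a raw-Mahalanobis-caliper mode behind
`caliper_metric = "mahalanobis"`. Exposed patients with no admissible
candidate are dropped and counted. The matched sets are evaluated by a
Cochran–Mantel–Haenszel test: the MH common odds ratio, a CI from the
Robins–Breslow–Greenland variance, and a one-sided p from the signed CMH
statistic without continuity correction (strata with an empty margin
contribute nothing and are dropped; we rely on the asymptotics of the summed
statistic rather than per-stratum corrections).

## Federation

Sources never exchange patient-level data. Three pooling routes, one per
estimator:

* adjusted coefficients by inverse-variance weighting,
  $\hat\beta_{pooled} = \sum_i \hat\beta_i/Var(\hat\beta_i) \,/\, \sum_i 1/Var(\hat\beta_i)$,
  with $Var(\hat\beta_{pooled}) = 1/\sum_i 1/Var(\hat\beta_i)$;
* unadjusted tables by a CMH test with *source* as the stratifier
  (a 2 × 2 × #sources array);
* matched strata by concatenating the per-source stratum tables into one
  2 × 2 × (k₁ + … + k_m) array and running a single CMH test.

Per-source RRRs are pooled by the same inverse-variance rule. Pooled
p-values are always recomputed from the pooled statistic, never combined
from per-source p-values. A source whose fit fails is dropped from the
affected pooled result with a warning instead of aborting the study —
matching how a registry cohort with an incompatible outcome definition is
reported alongside, not pooled. The `pool_*` functions accept only aggregate
objects (estimates, tables, stratum arrays); none of their signatures admit
patient-level confounders.

## Sensitivity analysis

* **E-values.** With rare outcomes the OR is identified with the RR
  directly (no square-root transform); protective ORs are inverted to a
  magnitude RR* ≥ 1 and $E = RR^* + \sqrt{RR^*(RR^*-1)}$. The CI E-value
  uses the bound nearer 1 and is set to 1 when the interval crosses 1.
  Reported values are rounded half-up to one decimal alongside full
  precision. This identification choice exactly reproduces the four
  published sensitivity values from the published ORs and CI bounds
  (0.70 → 2.2, 0.99 → 1.1, 0.86 → 1.6, 0.91 → 1.4), which the acceptance
  script recomputes.
* **Alternative estimators.** Hájek-normalized IPW outcome means (ATT) on
  the risk-difference and OR scales, and the doubly robust AIPW estimator
  with cross-fitted per-arm logistic outcome regressions, both with
  influence-function variances.
* **Exposure-window redefinition.** `exposure_window_variant()` reruns the
  whole pipeline with a 90-day MPR window and reports the Jaccard overlap of
  the exposed sets next to both result sets.
* **Pre-index health trends.** Per-arm proportions with any inpatient
  admission in each 30-day window before index, with Clopper–Pearson 95%
  CIs: parallel declining trends support comparability of the arms.

## What the generator emulates, and what it does not

`dgp_config()` defaults define the reference conditions used throughout the
tests: 20,000 patients per source, a true conditional OR of exp(−0.357) =
0.70 for exposure on ventilation, confounding strength 0.5 (age and a latent
comorbidity burden jointly shift exposure and outcome), a 10% baseline
ventilation rate, 15% exposure prevalence, 4% planted partial users, and
death-given-ventilation probability 0.45. These are choices a
pharmacoepidemiologist would call realistic for an elderly male inpatient
ARD population — e.g. alpha-blocker use around 15% in men 45–85, and roughly
one in ten index admissions ventilated — and they are fixed once, not tuned.
Two dialects mirror the structural quirks of real warehouses: an
employer-claims source (ages 45–65, in-hospital death flags, one contiguous
ICD-9 era) and a commercial/Medicare source (ages 45–85, registry death
months, a calendar gap spanning the ICD transition). Ventilation is drawn
first and death conditionally on ventilation, so the composite outcome is
well defined by construction; time is internally day-resolved, and the
month-dialect coarsens death dates to months only when tables are written.

A potential-outcomes oracle (`true_marginal_effect()`) simulates both
potential outcomes for a large synthetic population and returns the marginal
OR and RRR the DGP implies. Because logistic models are noncollapsible, the
marginal OR is not exp(true_log_or); the gap closes as the baseline rate
tends to zero, and the parameter-recovery tests compare estimates against
the oracle, not against the conditional coefficient.

The generator does **not** emulate: real ICD vocabularies (a representative
two-code-per-concept set stands in; any code list file can be substituted),
female or younger patients, treatment during the index stay, seasonality,
informative enrollment gaps, or utilization distributions beyond a negative
binomial with burden-dependent means — the last is a modeling choice with no
external anchor. Passing tests therefore demonstrate internal validity of
the pipeline under a claims-shaped DGP with known truth, not fidelity to any
particular warehouse.

## Numerical and reproducibility choices

* Seeds: every stage seed derives from one master seed by a rolling
  polynomial hash of the stage's label path (`derive_seed()`), so inserting
  a stage never perturbs the others; all seeds stay below 2^31. Identical
  configs give byte-identical JSON outputs, and the serialized analysis plan
  is hashed into every report before execution.
* Quantiles by linear interpolation (type 7); trimming uses a closed
  interval; degenerate (constant) score vectors keep everyone.
* Standardization tolerances of 1e-8 are asserted in tests; constant
  columns standardize to zero rather than NaN.
* Separation in the weighted logistic fit (non-convergence or |beta| > 15)
  raises an error carrying the event count, never a silent estimate.
* Matching ties in distance are broken by candidate index for
  reproducibility; Mahalanobis uses the trimmed-sample covariance with a
  1e-8 ridge.
* Empty cohorts and degenerate tables signal explicit conditions
  (`warning` for an empty cohort, errors naming the degeneracy) rather than
  crashing or returning NaN.

## Test problem sizes

The suite exercises the reference conditions directly: 100 federated
replicates at 20,000 patients per source for parameter recovery (coverage of
the oracle marginal OR, bias reduction relative to the crude estimate, and
sign consistency), and 500 replicates at n = 2,000 under a randomized null
for one-sided type-I error of all three pipelines. Exact components are
verified against brute-force oracles: hypergeometric tail sums recomputed
from binomial coefficients over every 2x2 table with n ≤ 40, hand-evaluated
Mantel–Haenszel and inverse-variance formulas, and `mantelhaen.test` /
`fisher.test` as independent cross-checks of our CMH machinery.

## Known limitations

* The delta-method RRR variance is first-order (see above); pooled RRR
  weights inherit that approximation, and no RRR CI is emitted by default.
* The adjusted estimator reports a conditional(-on-covariates, ATT-weighted)
  log OR; users comparing against marginal targets should use the oracle's
  marginal OR, as the tests do, and mind noncollapsibility.
* Greedy matching without replacement is order-dependent by nature; we make
  it reproducible (seeded order), not order-free. Optimal matching is out of
  scope.
* Fisher's exact one-sided test is discrete and mildly conservative at
  small counts; type-I control is asserted empirically at n = 2,000, not
  proven at all n.
* The CLI-style entry points of a workflow tool are deliberately absent:
  `run_study()` plus a config object is the interface, in keeping with how
  analysis packages in this space are used.
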