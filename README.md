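# fedclaims

Federated retrospective causal analysis of medication exposure and
respiratory outcomes in insurance-claims-shaped data.

## The problem

Alpha-1 adrenergic receptor (alpha-1-AR) antagonists — tamsulosin,
doxazosin and relatives — are taken chronically by millions of older men for
benign prostatic hyperplasia, a condition unrelated to the immune system.
Preclinical work suggests this drug class can interrupt the
catecholamine-cytokine amplification loop that drives hyperinflammation in
severe lower respiratory tract infection. The epidemiological question:
among older men hospitalized with acute respiratory distress (ARD) or
pneumonia, do prior regular users of alpha-1-AR antagonists have lower odds
of mechanical ventilation, and of ventilation followed by death, than
non-users?

Answering it from claims data requires a target-trial emulation across
several license-restricted databases that may not pool patient-level
records. `fedclaims` implements that pipeline end to end for
biostatisticians and pharmacoepidemiologists:

* a **synthetic multi-source claims generator** with confounding by
  indication, source-specific coding dialects, and a potential-outcomes
  oracle, so every stage is testable against a known ground truth;
* a **cohort builder** applying the study definitions — medication
  possession ratio (MPR) >= 50% over the prior year for exposure (partial
  users excluded), first qualifying inpatient admission as index, age 45-85,
  12-month enrollment, standardized confounders — with CONSORT accounting;
* three **estimators** per source: Fisher exact (unadjusted),
  propensity-trimmed inverse-propensity-weighted logistic regression with
  sandwich variance (adjusted), and 5:1 exact-age greedy Mahalanobis
  matching evaluated by the Cochran-Mantel-Haenszel test (matched);
* **federation** without raw-data exchange: inverse-variance pooling of
  coefficients and of relative risk reductions,

  beta_pooled = (sum_i beta_i / Var(beta_i)) / (sum_i 1 / Var(beta_i)),
  Var(beta_pooled) = 1 / sum_i 1/Var(beta_i),

  and CMH pooling over source strata or concatenated matched strata;
* **sensitivity analyses**: E-values (E = RR* + sqrt(RR*(RR*-1)) on the
  risk-ratio scale), IPW/AIPW alternative estimators, a 90-day
  exposure-window variant, and pre-index health-trend comparison.

See `vignettes/federated-claims-analysis.Rmd` for the full methods account.

## Worked example

```r
library(fedclaims)

cfg <- study_config(
  dgp = dgp_config(n_patients = 5000),   # two sources, true conditional OR 0.70
  methods = c("unadjusted", "adjusted", "matched"),
  master_seed = 2026
)
res <- run_study(cfg)
print(res)
```

```
<study_result> plan hash 72dffa0a4ef2c575
 diagnosis          exposure     outcome     method   rrr    or            ci
       ARD any_alpha_blocker ventilation unadjusted 12.8% 0.860 (0.695-1.064)
       ARD any_alpha_blocker ventilation   adjusted 21.0% 0.753 (0.603-0.939)
       ARD any_alpha_blocker ventilation    matched 10.9% 0.825 (0.650-1.047)
       ARD any_alpha_blocker  vent_death unadjusted 16.4% 0.829 (0.610-1.126)
       ARD any_alpha_blocker  vent_death   adjusted 25.6% 0.720 (0.523-0.991)
       ARD any_alpha_blocker  vent_death    matched 15.1% 0.783 (0.558-1.100)
        p    n
  0.08175 7724
 0.005888 7490
   0.0556 2423
   0.1148 7724
  0.02188 7490
   0.0812 1365
```

Each row pools the two synthetic sources federatedly for one
exposure-outcome-method cell: RRR is the pooled relative risk reduction, OR
the pooled odds ratio with its 95% CI, `p` the one-sided p-value in the
protective direction, and `n` the pooled analysis sample (matched rows count
informative matched sets only). The true conditional OR planted in the
generator is 0.70; the crude estimate is pulled toward 1 by confounding by
indication, and the adjusted estimate recovers the truth. The oracle check
and the unmeasured-confounding sensitivity of the composite-outcome result:

```r
ora <- true_marginal_effect(cfg$dgp, n_mc = 2e5, seed = 1)
sprintf("oracle marginal OR (ventilation): %.3f", ora$marginal_or)
#> "oracle marginal OR (ventilation): 0.703"

pl <- res$pooled[["ARD.any_alpha_blocker.vent_death.adjusted"]]
evalue(pl$or_pooled, pl$ci95[2])
#> <evalue> OR 0.72 -> E-value 2.1 (point), 1.1 (CI bound)
```

An unmeasured confounder would need an association of about 2.1 (risk-ratio
scale) with both exposure and outcome to explain this estimate away, and
about 1.1 to move the interval to include 1.

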