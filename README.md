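# cmcflow

Statistics for droplet-based photoacoustic enumeration of circulating
melanoma cells (CMCs) and for CMC-threshold metastasis risk stratification
in early-stage (I–III) melanoma.

Pigmented melanoma cells absorb pulsed laser light and emit ultrasound, so
they can be counted label-free in blood: two-phase flow splits 1 ml of
cell suspension into ~1000 one-microlitre droplets, each droplet is
interrogated by a laser pulse, and droplets whose acoustic signal exceeds
3x the blank noise floor are scored positive. `cmcflow` is aimed at
researchers analysing such rare-cell enumeration assays and at
biostatisticians studying CMC-count-based progression models. It provides:

* **Droplet occupancy statistics.** With `N` cells mixed into `n` droplets,
  occupancy is Poisson, `P(k) = exp(-λ) λ^k / k!` with `λ = N/n`. The
  package gives the closed forms (expected occupied droplets
  `n(1-exp(-λ))`, multiple-occupancy probability `1-exp(-λ)(1+λ)`), a
  seeded synthetic droplet-train simulator with amplitude thresholding,
  and the occupancy-corrected estimator `N̂ = -n log(1 - m/n)` for `m`
  positive droplets.
* **Risk stratification.** A bundled 38-patient study cohort (per-patient
  lowest/highest CMC counts, metastasis status, follow-up days), strict
  threshold classification (`> 2` CMCs/ml on any occasion), a 2x2
  contingency table with an exact two-tailed Fisher test implemented from
  hypergeometric enumeration, a threshold sweep, follow-up summaries, and
  high-threshold risk fractions.
* **Cluster diagnostic.** Centroids of the metastatic/nonmetastatic sample
  clouds in (day, count) space and their Mahalanobis distances
  `sqrt((c_g - m)' Σ⁻¹ (c_g - m))` to the pooled data.
* **Longitudinal hazard model.** `h(t) = h0(t) exp(β X(t) + α Z)` with a
  step-function CMC covariate `X(t)` and ordinal stage `Z`: a synthetic
  longitudinal cohort generator and a from-scratch partial-likelihood
  fitter (Newton–Raphson, Breslow ties, time-varying covariates).

## Worked example

```r
library(cmcflow)

co <- bundled_study_cohort()
g  <- classify_by_threshold(co, threshold = 2)
c(low = nrow(g$low), high = nrow(g$high))
#> low high
#>  11   27

followup_summary(g$low)
#> $n: 11   $mean_days: 1288   $median_days: 1186

fisher_exact_two_tailed(study_contingency_counts())
#> [1] 0.000166027

high_threshold_risk(co, 100)
#> $n_at_risk: 7  $n_metastatic: 5  $pct: 71.42857  $pct_display: 71
```

None of the 11 patients who never exceeded 2 CMCs/ml progressed to
metastasis over a mean 1288 days of follow-up, while the association
between exceeding the threshold and progression is strongly significant
(exact two-tailed p ≈ 0.00017, printed as 0.0002); risk climbs to 71% above
100 CMCs/ml and 80% above 200. `reproduce_paper()` prints every recomputed
aggregate next to its published value, flagging the quantities affected by
a known one-row discrepancy between the study's printed per-patient tables
(17 metastatic) and its published contingency counts (18).

The droplet model in one line: 33 cells over 1000 droplets are expected to
occupy `expected_occupied(33, 1000, "exactly_one")` = 31.93 → 32 droplets
singly, which is why "one positive droplet = one cell" is accurate at
clinical CMC loads.

Synthetic end-to-end run of the hazard model:

```r
co  <- synthesize_cohort(synthetic_cohort_config(n_patients = 1000, rng_seed = 1))
fit <- fit_cox(co)   # truth: beta = 0.5, alpha = 0.3
fit$coef
#>      beta     alpha
#> 0.5398 0.3365
```

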