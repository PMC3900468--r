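---
title: "Validating an additive self-report dementia risk index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating an additive self-report dementia risk index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anuadri)
```

## The index

The ANU-ADRI is an additive point score for late-life Alzheimer's disease
(AD) risk built entirely from self-report items. Unlike indices fitted to a
single cohort, its weights come from evidence synthesis: for each factor the
pooled relative risk across published cohort studies is converted to a
beta-weight (its natural logarithm), scaled by a common constant, and
rounded to an integer — `derive_points()` implements this rule, rounding
half away from zero so that protective ratios below 1 map to negative
points. The bundled point table (`inst/extdata/anu_adri.json`), not the
derivation rule, is the source of truth for the weights.

An individual's score is the sum of the points of the category they occupy
on each factor. Age is the only sex-stratified factor: the same integer age
bands (<65, 65–69, …, ≥90) carry different points for men and women, and a
participant's points come from the sex-matched stratum. Ages are floored to
whole years before banding, so 64.6 falls in "<65" — the bands are
integer-year categories. Because scoring is a plain sum, the theoretical
range of any scorecard is the sum of per-factor extrema
(`theoretical_range()`); for the 10-factor cohort variant this is −13 to 64
and for the 9-factor variant −11 to 56, both exactly recomputable from the
point table. For the 8-factor variant, summing the per-factor extrema gives
−3 to 64; a maximum of 61 has also been quoted for that variant, which
cannot be reconstructed from the printed per-category points, so the package
reports the computed value.

Two table entries need conventions of their own:

* **Heavy alcohol.** The point table leaves the heavy-drinking category
  blank. The package defaults it to 0 — the same as abstainers, making the
  light-to-moderate category's −3 the only alcohol contribution — and
  exposes it as an override
  (`build_scorecard("anu_adri_full", overrides = list(alcohol = c(heavy = 2)))`)
  for users who prefer a positive weight.
* **Counting factors.** Age and gender are a single stratified factor
  internally but count as two when a variant is described as having "10
  factors", matching how the index is usually described. `scorecard_factors(card,
  counted = TRUE)` returns both views.

Cohort variants restrict the full card to the factors a given study actually
measured; the Kungsholmen variant additionally drops the "former smoker"
category because that study asked only about current versus never smoking.
The common-variable card (age, sex, education, diabetes, smoking, alcohol)
is the intersection used for cross-cohort comparison. The CAIDE comparator
is a midlife index over age, sex, education, cholesterol, systolic blood
pressure, physical activity and obesity; its numeric weights are not
restated alongside the validation cut-offs, so the package bundles the
original derivation-cohort weights mapped onto the dichotomous late-life
cut-offs (age >47 years, female, <10 years education, cholesterol
>6.5 mmol/L, SBP >140 mm Hg, inactive, BMI ≥30 kg/m²), overridable like any
scorecard. Following the validation framing, female sex is treated as the
point-carrying category.

## Missing data

The reported analyses this pipeline mirrors are complete-case, so
`missing_policy = "strict"` is the default everywhere: a record missing any
factor required by the card is excluded by `filter_analysis_set()` (and
scoring such a record is an error). The `"skip"` policy instead lets missing
factors contribute 0 points — the reference-category value — and records
which factors were skipped. Multiple imputation is deliberately out of
scope.

## The synthetic cohort generator

No participant-level data are distributed with the index, so the generator
(`synthetic_config()`, `simulate_cohort()`) stands in for the three
validation cohorts. What it reproduces:

* **Marginals.** Sex ratio, the per-sex age-band distribution, and every
  categorical factor's published frequency table, per cohort preset
  (`map_like`, `kp_like`, `cvhs_like`). Frequencies are the published counts
  renormalised over observed categories.
* **Factor availability.** Each preset carries only the factors its cohort
  measured, so a `cvhs_like` fixture has no TBI column and a `kp_like`
  smoking column contains only never/current.
* **Follow-up.** Censoring times are exponential with mean equal to the
  cohort's published mean or median follow-up (3.5 years for `map_like`,
  6 years otherwise).
* **Outcome.** Event times are exponential with rate
  `baseline_hazard · exp(beta_per_point · (score − mean score))` — the
  simplest proportional-hazards data-generating process. Centring on the
  realised mean score keeps `baseline_hazard` (default 0.02/year, an
  old-age dementia incidence of roughly 2 per 100 person-years)
  interpretable as the hazard of an average-scoring participant. An
  observed event is AD with probability `ad_fraction` (default 0.75, the
  commonly cited share of AD among dementias).

What it does **not** reproduce, and what that means for the tests: factors
are sampled independently because only marginals are published, so the
synthetic score distribution is narrower-tailed than a real cohort's, where
risk factors cluster; there is no competing risk of death, no informative
censoring, and no age-dependence of the baseline hazard. Tests passing on
these cohorts therefore demonstrate that the pipeline's statistics are
correct and recover a known generating model — not that the index attains
any particular discrimination in real populations. `beta_per_point`
(default 0.05 per point on the log-hazard) was chosen to give the
dose-response tests power at the simulated sample sizes, not as a
biological estimate. Uncorrelated binary CAIDE variables with plausible
prevalences are generated alongside so the comparator stage can run end to
end.

Determinism: every draw is a function of the configuration and its seed.
Factor sampling, outcome simulation and missingness injection use seed,
seed + 1 and seed + 2 respectively, so the covariate and event-time uniform
streams never overlap. `missing_rate` knocks out factor cells completely at
random; a rate of `1 − (903/1164)^(1/8)` per cell reproduces a 78%
complete-case fraction over eight factor columns, the retention the
10-factor cohort reported.

## Statistical pipeline

* **c-statistic.** Computed on incident-case status over follow-up (the
  Mann–Whitney form over all case–control score pairs, ties counted half),
  not a time-dependent concordance — matching how validation AUCs for these
  indices are reported. Confidence intervals use DeLong's placement
  variance with a normal interval truncated to [0, 1]; perfectly separated
  (zero-variance) inputs get a zero-width interval. A seeded percentile
  bootstrap (2000 resamples) is available for cross-checking.
* **Quartiles.** Cut points are the 25th/50th/75th sample percentiles under
  the linear-interpolation quantile definition, and intervals are
  `(−∞,q25], (q25,q50], (q50,q75], (q75,∞)`: a score tied with a boundary
  goes *down*, which is what the half-open "x.1–y" printed quartile ranges
  imply. Integer scores tie heavily, so quartile sizes are only
  approximately n/4; coincident boundaries are collapsed with a warning.
* **Incidence.** `1000 × events / person-years` per quartile, with
  zero-event quartiles flagged rather than given a spurious interval.
* **Cox models.** `survival::coxph` with Breslow tie handling by default
  (Efron available) — with many tied integer scores the tie method is worth
  fixing explicitly. Quartile hazard ratios come from indicator contrasts
  against quartile 1 with Wald intervals; the linear trend p is the Wald
  test of a second model with quartile entered as an ordinal 1–4 covariate.
  Monotone-likelihood fits (a quartile with no events) are flagged and
  their interval reported as unbounded instead of a misleading finite one.
* **Age split.** Quartiles are computed on the full sample first, then each
  quartile's 2×2 table of age group (< versus ≥ the split age, default 70)
  by case status is tested with Pearson's chi-square, 1 df, no continuity
  correction; quartiles with an empty age group report an undefined
  statistic.
* **Subgroups.** The common-variable AUC is computed on exactly the same
  analysis set as the full card — no re-filtering to a different n — so the
  difference between the two AUCs isolates the effect of dropping factors,
  not of changing the sample.

## Problem sizes and test design

The test suite checks the two statistical engines against independent
oracles: the c-statistic against exhaustive pairwise concordance counting
(hundreds of random instances up to n = 50, exact equality), and the Cox
engine against a closed-form three-subject maximum (−½ ln 2) and numeric
maximisation of the Breslow partial likelihood on random ≤6-subject
datasets (1e-6 agreement). Pipeline-level behaviour is checked by parameter
recovery: cohorts of n = 5000 at 20 seeds recover a generating per-point
log-hazard of 0.05 inside the 95% CI and produce strictly increasing
quartile hazard ratios with trend p < 0.001 in at least 18 of 20; 500
null-effect cohorts of n = 400 keep the trend-test rejection rate at
5% ± 2%; marginal fidelity is checked at n = 10,000 against 3-SE binomial
bands. These sizes were chosen to give the recovery and calibration checks
conventional power while keeping the default suite quick to run.

## Known limitations

Beyond the generator simplifications above: the package does not implement
calibration statistics, net reclassification, time-dependent ROC or
competing-risks models; it treats all cohorts as simple random samples
(no two-phase sampling weights); and it does not map raw instrument scores
(CES-D items, MET minutes, food-frequency servings) to categories beyond
the documented cut-offs — inputs are expected already categorised per the
data dictionary in `read_cohort_csv()`.
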