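---
title: "Externally validating non-invasive diabetes risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Externally validating non-invasive diabetes risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2dval)
```

## The problem

Non-invasive risk scores — short questionnaires plus simple anthropometry —
are used to triage who should receive a confirmatory blood test for
undiagnosed type 2 diabetes (T2D). A score developed in one population
rarely transfers unchanged to another: its ranking of individuals may still
be useful (discrimination), while its absolute risk estimates are off
because baseline prevalence differs (calibration). External validation
quantifies both, and intercept-update recalibration repairs the second
without touching the first.

`t2dval` packages this workflow for cohorts with up to three visits per
participant and two diagnostic definitions of screen-detected T2D: fasting
plasma glucose (FPG) ≥ 7 mmol/L, or HbA1c ≥ 6.5%. Because the two analytes
identify overlapping but unequal case sets, every statistic is computed
separately under each criterion.

## Cohort assembly

One analysis record per participant is built from the visit table:

* a participant is a **case** if the active criterion's analyte is at or
  above threshold at any visit; the record is taken at the *earliest* such
  visit (the first time of diagnosis), so case predictors are measured at
  diagnosis, not at baseline;
* a **noncase** must be below threshold at *every* visit where the analyte
  is present, and contributes the baseline (visit 1) record;
* participants on diabetes medication at any visit are excluded (their
  glycaemia is treated, so screen-detection semantics do not apply), as are
  participants whose analyte is missing at every visit. Nothing is imputed;
  every exclusion is logged with a reason.

A missing analyte at a single visit yields an *indeterminate* status at
that visit, never a silent noncase. A participant missing the analyte at
some visits is a noncase only if below threshold at all visits where it is
present — a deliberately conservative reading, since the alternative
(requiring presence at all visits) would discard most of a real cohort.

**Hypertension** is a composite predictor: self-reported hypertension, OR
blood-pressure medication, OR measured BP ≥ 140/90 mmHg. Some scores
(FINDRISC) were defined on medication use alone, so each score spec
declares which definition it consumes (`clinical` vs `medication_only`).

**Complete-case filtering is model-specific.** Each score drops exactly the
records missing one of *its* predictors, so models are validated on
different n — a faithful rendering of how missing family-history data
shrinks the cohorts of scores that use it while leaving a three-item score
untouched. The 100-events/100-non-events precision rule is checked per cell
and surfaced as a warning, never as an error.

## Risk scores as configuration

A score spec is a declarative JSON/YAML document: items (predictor +
categorisation + points or coefficients), a form (`points` or `logistic`),
and a probability link. Category intervals are lower-inclusive half-open
`[lo, hi)`, matching the ≥ conventions of the published cut points; sex-specific
cut points are supported (waist circumference in FINDRISC and IRS).
Point scores do not natively emit probabilities, and the validation
statistics need them, so each points spec carries a `score_logistic` link
`p = plogis(a + b·s)` whose parameters live in the spec file — the engine
stays model-agnostic, and the (provisional) link is part of the score's
configuration, reconstructed from each source's published risk-per-score
data. The bundled ADRS file deserves emphasis: the original coefficients
are unpublished, so the shipped spec is a clearly flagged provisional
reconstruction of the described model (logistic in age, waist
circumference, hypertension), adequate for exercising the pipeline but not
a claim about the real ADRS.

## The statistics

Let `p_i` be predicted probabilities and `y_i` case indicators.

* **C-statistic**: pairwise concordance with ties counted half, computed by
  midranks in `O(n log n)`. The standard error is the DeLong
  structural-components estimator (the conventional nonparametric choice);
  the 95% CI is normal-theory, truncated to [0, 1]. Subgroup C-statistics
  are compared with an independent-samples z-test — the strata are
  disjoint, so the paired DeLong covariance term vanishes.
* **ROC and thresholds**: classification is `p ≥ t`; the returned polyline's
  trapezoidal area equals the C-statistic to numerical precision (a test
  enforces 1e-12). Optimal thresholds are reported by the Youden index and
  by the top-left distance; ties resolve to the lowest threshold. Both are
  computed because published tables rarely state which rule produced their
  "optimal threshold"; reports label the Youden values as primary.
* **E/O**: `Σp / Σy`, with the observed count treated as Poisson. The
  default interval is the log-normal approximation `E/O · exp(∓z/√O)`;
  exact Garwood limits are available behind `exact = TRUE`. Sums or means
  give the identical ratio; sums are used.
* **Brier score**: `mean((p − y)²)`, 0 = perfect. (Some descriptions invert
  this scale and call 1 perfect; observed values in validation tables are
  only consistent with the standard lower-is-better convention, which is
  what is implemented.)
* **Yates slope**: `mean(p|y=1) − mean(p|y=0)`.
* **Hosmer–Lemeshow**: deciles of predicted risk (quantile bins, merged on
  ties; g = 10 by default, the conventional choice),
  `χ² = Σ (O_b − E_b)² / (E_b(1 − p̄_b))`. Degrees of freedom follow the
  data's role: on *external validation* data no parameters were estimated
  from the sample, the statistic is asymptotically `χ²_g`, and referring it
  to `g − 2` df inflates the type-I error to ≈ 11% at the 5% level — so the
  default is `df = g`, with `df = g − 2` available via
  `data_role = "development"`. A Monte-Carlo test pins the default's
  type-I error to [2%, 9%].

## Recalibration

The correction factor is the log odds ratio of observed prevalence to mean
predicted risk, `Δ = ln[odds(prev)/odds(p̄)]`, added to every linear
predictor. One-step application (the default, matching standard practice)
moves E/O toward 1 but does not reach it exactly when probabilities are
heterogeneous — the mean of shifted probabilities is not the shifted mean.
An `iterated` mode repeats compute-then-apply until `|E/O − 1| < 1e-6`
(typically 3–5 iterations); outputs label which mode produced them. Both
modes are strictly monotone transformations, so the C-statistic is
unchanged — asserted to 1e-12 in every report cell. Subgroup statistics are
computed on recalibrated probabilities using the overall correction factor
(per-stratum refactoring is available behind a flag), since published
subgroup tables describe "the recalibrated models" without stratum-specific
updates.

## The synthetic cohort generator

No individual-level data from the motivating study are deposited, so the
generator emulates its published structure and serves as the package's test
bed. Defaults (all overridable in `sim_config()`):

| Parameter | Default | Rationale |
|---|---|---|
| n, visits | 937 × 3 | published analytical cohort size and design |
| female fraction | 0.70 | published descriptive |
| age | trunc-normal(52, 10), ≥ 30 | eligibility ≥ 30, median ≈ 51–52 |
| BMI | log-normal, median 25 | median split at 25 is the subgroup cut |
| waist | 24/28 + 2.4·BMI + N(0,6) cm | realistic sex-specific WC–BMI relation |
| rural fraction | 0.56 | read off published stratum sizes (527/410) |
| family history | 14% yes, 40% missing | published missingness |
| FPG / HbA1c prevalence | ≈ 0.14 / 0.26 | published prevalences; intercept −2.53 and shift +0.88 calibrated by Monte Carlo |
| latent correlation ρ | 0.7 | gives realistic FPG/HbA1c case-set discordance; no published estimate exists |
| diagnosis visit | 0.80/0.12/0.08 | most prevalent cases detectable at baseline |
| medication among severe cases | 0.05 | exercises the exclusion rule without distorting prevalence |

The true risk model is logistic in centred age, waist circumference,
clinical hypertension and sex. Case status under each criterion comes from
a *correlated bivariate latent*: standard-normal `(z₁, z₂)` with
correlation ρ, participant `i` an FPG-case iff `Φ(z₁) < plogis(η_i)` and an
HbA1c-case iff `Φ(z₂) < plogis(η_i + 0.88)`. This construction makes the
any-visit case probability *exactly* the true model's logistic probability
(enabling exact recovery tests) while letting the two criteria disagree on
individuals, as the real analytes do. Analyte values are then drawn from
class-conditional truncated normals that respect the diagnostic thresholds
by construction. Cases are allocated a first-diagnosis visit; pre-diagnosis
visits carry below-threshold values.

**What recovery tests mean.** The true model parameterises the baseline
cross-section (visit-1 covariates, any-visit case status), so recovery
experiments — correction factor ≈ 0, recalibrated E/O ≈ 1, C within its CI
of the Monte-Carlo implied AUC (≈ 0.74 at defaults) — are run on
`baseline_cross_section()`. The assembled analysis dataset intentionally
differs: cases carry diagnosis-visit covariates (they are older at
diagnosis) and medicated cases are excluded, so recovery there is
approximate by design. That asymmetry mirrors the real design and is a
feature, not a defect.

**What the generator does not emulate.** Missingness is MCAR only (no
mechanism is published); covariate correlations beyond the stated marginals
and the WC–BMI link are not reproduced; within-person analyte values across
visits are conditionally independent given case status; there is no OGTT
criterion. Passing tests therefore demonstrate the *pipeline's*
correctness under a faithful study structure, not the reproduction of any
real cohort's numbers — the published headline values were computed on
undeposited data and are not reproducible at desk scale, which is why the
package's acceptance checks are oracle- and property-based.

## Numerical choices and edge cases

* Concordance and its variance use midranks, exact under ties.
* Quantile bins merge tied boundaries; the Hosmer–Lemeshow test refuses to
  run with fewer than 3 usable bins; a degenerate zero-variance bin with
  `O = E` contributes 0.
* `eo_ratio` errors on zero observed cases (undefined ratio);
  `recalibration_factor` errors when prevalence or mean risk touch {0, 1}.
* Median splits send ties to the upper group; BMI splits at the fixed 25.
* Iterated recalibration caps at 100 iterations and errors rather than
  returning an unconverged result.
* Every simulation entry point takes an explicit seed and is byte-identical
  under it; `withr::with_seed` keeps the caller's RNG state untouched.
* Test and acceptance problem sizes (500 oracle instances at n ≤ 50, 200
  threshold scans, 200 Hosmer–Lemeshow replicates at n = 1000, 500 coverage
  replicates at n = 200, recovery at n = 10 000 and 100 perturbation
  replicates at n = 2000) were chosen so the whole suite completes in about
  a minute while holding Monte-Carlo error well inside the asserted bands.

## Known limitations

* The bundled score specs are provisional transcriptions/reconstructions;
  validating the *real* scores requires replacing the spec files with
  coefficients from the primary sources.
* The independent-samples z-test for subgroup C-statistics assumes large
  strata; with very few cases (< 10, flagged in output) it is anticonservative.
* One-step recalibration is exact only for homogeneous probabilities; use
  `iterated` when exact aggregate calibration matters.
* The generator's latent-correlation default (ρ = 0.7) is a judgement call;
  sensitivity analyses can sweep it through `sim_config()`.
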