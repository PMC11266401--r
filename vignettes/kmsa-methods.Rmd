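---
title: "Censoring-adjusted attributable costs from matched claims cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censoring-adjusted attributable costs from matched claims cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmsacost)
library(data.table)
```

## The estimation problem

Administrative claims give complete billing histories for whole populations,
which makes them the natural source for the *economic* burden of a newly
diagnosed disease: how much more healthcare does a patient consume after
diagnosis than a demographically identical person without the disease?  Two
features of claims follow-up make the naive answer wrong:

* **Administrative censoring.**  A database ends on a fixed date.  Patients
  diagnosed late in the accrual window contribute one year of follow-up,
  patients diagnosed early contribute three.  Summing observed costs
  underestimates multi-year cumulative cost; restricting to patients with
  complete potential follow-up is also biased, because late-diagnosed
  patients stay in that "complete" subset only by dying (death terminates
  observation legitimately), so decedents are over-represented.
* **Zero-inflation and skewness.**  Per-period costs are a mass at zero plus
  a long right tail, so a single linear model fits badly.

`kmsacost` implements the standard remedy — a partitioned,
survival-weighted ("Kaplan-Meier sample average", KMSA) estimator with
two-part regression models and recycled predictions — around an exactly
matched case/comparator design, plus a calibrated synthetic claims
generator so the whole pipeline is testable without access to confidential
claims.

## Design: cohorts from claims

**Case identification.**  A patient becomes a case on the date of their
first claim bearing a qualifying diagnosis code (default ICD-10 E85.4,
E85.8, E85.9), provided they have at least one inpatient claim or at least
two outpatient claims with a qualifying code in any diagnosis position,
some outpatient pair at least 30 days apart (evaluated as last minus first,
which is equivalent to the existence of such a pair), and a biopsy
procedure claim within the closed window from 365 days before to 182 days
after the index date.  Candidates are then excluded, in fixed order with
one recorded reason each, if they carry the legacy ICD-9 amyloidosis code
277.3 in 2015, a non-AL flag in the catastrophic-illness registry, or any
post-index claim with a "switch" code (E85.0, E85.1, E85.2, E83.3 — the
last implemented as published although it is plausibly a typo for E85.3;
it is configurable in `case_criteria()`).

**Matching.**  Each case receives `ratio` (default 10) comparators agreeing
exactly on sex, region, and age in completed years at the case's index
date, drawn uniformly without replacement; a comparator serves at most one
case and must be alive on the reference date it inherits.  Because a
greedy sequential draw can strand a later case even when a full assignment
exists, `match_comparators()` repairs shortfalls with an augmenting-path
search over key-compatible cases; the insufficient-pool error is raised
only when no valid assignment exists.  Exact-year age matching is the
strictest reading of "matched on age" and is what the generator guarantees
feasible; a `age_widen` fallback (±1 year) exists but is off by default.

**Comorbidities.**  Six categories (cardiac, liver, renal, pulmonary,
neuropathy, malignancy) are flagged from the baseline year
`[index − 365, index − 1]` by prefix-matched codes with the usual
claims-algorithm rule: one inpatient or two outpatient claims.  Two
same-day outpatient claims count as two — unlike the case rule, no gap or
distinct-date requirement applies.  The shipped code lists are illustrative
stand-ins (the study-specific supplementary lists are not public) and are
fully replaceable.

## The estimator

Follow-up is partitioned into seven periods: four year-1 quarters of
91/91/91/92 days, two year-2 half-years, and one year-3 period, so that
year boundaries land exactly on days 365/730/1095.  This is the collapsed
form of a 12-quarter partition (available as
`period_scheme("quarterly")`); collapsing years 2–3 reflects the flat
mortality hazard there and stabilises the per-period fits.

For each cohort, component and period $p$ a two-part model is fitted on the
patients under observation in $p$ (status `complete` or `died_within`;
periods cut by the database end are excluded from fitting but keep their
partial costs in the panel):

$$\Pr(Y_{p}>0 \mid x) = \operatorname{expit}(x'\alpha_p), \qquad
  E[Y_{p} \mid Y_{p}>0, x] = \exp(x'\beta_p),$$

with a logistic part 1 and a log-link GLM part 2 (gamma family for costs,
negative-binomial for counts).  Covariates are age (continuous by default;
the registry age bands via `age_bands = TRUE`), sex, five region contrasts
and the six comorbidity indicators.  Degenerate configurations degrade
exactly rather than failing: an all-zero period is a structural zero, an
all-positive period fixes part 1 at 1, separation or too few positive rows
fall back to closed-form intercept-only fits (the log-link intercept MLE is
the log sample mean).  **Recycled predictions** standardise each fit over
the cohort's *full* baseline membership $\{x_i\}$, regardless of survival:

$$\mu_p = \frac1n \sum_i \operatorname{expit}(x_i'\alpha_p)\,
          \exp(x_i'\beta_p).$$

Averaging over each cohort's own covariate distribution (not the pooled
one) keeps each cohort's estimate self-contained, so the case-minus-
comparator subtraction is interpretable.

The KMSA estimate weights each period mean by the Kaplan-Meier probability
of being alive at the period start and accumulates:

$$\widehat{C}(h) = \sum_{p:\,s_p < h} \widehat{S}(s_p^-)\, \mu_p,
  \qquad h \in \{365, 730, 1095\}.$$

Death is the event; censoring is administrative only.  With day-resolution
event times the weight is evaluated just before $s_p$ (i.e. $P(T \ge s_p)$):
a patient who dies on a period's first day still contributes that period's
costs, so they must count as at risk — this also makes the period-1 weight
exactly 1.  `survival_at()` itself keeps the conventional
right-continuous $S(t) = P(T>t)$.

Attributable (incremental) quantities are case minus comparator per
component and horizon.  Components are modelled separately, so setting
components need not sum to the separately modelled total — only the raw
panel rows are additively consistent.

**Inference** is a non-parametric bootstrap over patients: each of B
(default 1000) replicates resamples both cohorts independently with
replacement at original size, refits the KM weights and every two-part
model, and recomputes all recycled predictions, cumulative and incremental
estimates.  Summaries are the replicate mean, SD and 2.5/97.5 percentile
interval.  Resampling deliberately breaks matched sets (a set-preserving
mode exists for sensitivity), and the weights are refitted per replicate
(a fixed-weights mode exists).  The per-component p-value is a two-sample
t-test on per-patient observed totals, computed once on the original data,
mirroring how such tables are usually footnoted.

## The synthetic world

The generator emulates the statistical structure the estimator assumes,
calibrated once to published cohort-level summaries; these defaults are the
stated world and are not tuned per experiment.

* **Demographics.**  Sex (59.07% male), six regions (published split, with
  the largest remainder category trimmed by 1/10,000 so the vector sums to
  one), and age drawn uniformly within published age bands; with the open
  band set to [80, 90) the mixture mean is 60.79 y against the published
  60.78.  The comparator pool is built by cloning cases on the matching
  keys, guaranteeing ≥ 10 exact twins per case.
* **Mortality.**  Piecewise-exponential with change-points at 90/182/1095
  days — the simplest family reproducing the three printed cumulative
  mortality values per cohort (8.4/12.1/18.8% for cases,
  0.05/0.9/3.7% for comparators) while keeping the early-mortality shape.
  Survival is independent of the administrative censoring time given
  covariates, which is exactly the independence the KMSA estimator needs.
* **Costs and HRU.**  Per period and setting, counts are negative binomial
  with mean proportional to alive-days, and positive costs are gamma — the
  right-skewed, overdispersed structure the two-part model targets.
  Year-1 case intensities are the published crude means (37.88 outpatient
  visits, 0.97 ER visits, 1.15 admissions, 12.02 hospital days; setting
  costs 179,740/108,450/6,300 NT$; medication share 121,250 NT$).  The
  generator converts annual targets into per-day rates by dividing by the
  analytic expected alive-days implied by the mortality model, so crude
  means (which include decedents' partial accrual) are matched, not just
  survivor means.  Comparator intensities are back-solved from published
  ratios and are therefore approximate; case year-2/3 count paths are
  chosen plausibly and scaled so annual totals hit the published 175,400
  and 152,180 NT$.  Every case receives a qualifying inpatient claim with a
  biopsy procedure code on the index date (30% carry the qualifying code in
  a secondary position); comorbidity flags are realised as two baseline
  outpatient claims with category codes; configurable "trap" patients
  carry each of the six broken patterns the cohort rules must reject.
  Covariate effects act multiplicatively on rates and positive-cost means
  and are normalised analytically (first and second moments of the
  multiplier under the cohort's covariate distribution) so population
  calibration targets are preserved exactly.
* **What the generator does not emulate.**  Dependent censoring, claim-level
  fee-schedule detail, correlated comorbidities (no printed joint
  distribution exists), within-year seasonality, and cost autocorrelation
  across periods beyond what shared covariates and survival induce.  A
  green test suite therefore establishes that the estimator recovers truth
  in a world satisfying its assumptions — not that those assumptions hold
  in any particular real database.

## Numerical choices and edge cases

* Dates are calendar dates externally and integer day offsets from index
  internally; periods are half-open `[start, end)`; the baseline year is
  `[index − 365, index − 1]` and a claim on the index date belongs to
  follow-up.
* Costs are integer NT$ in claims and double precision in all aggregates
  (cohort-level sums overflow 32-bit integers).
* The IRLS engine stops at 1e-10 relative deviance change (max 50
  iterations) and falls back to intercept-only fits on singularity,
  non-convergence or coefficient blow-up (|coef| > 30), so bootstrap
  replicates never abort.
* Printed-style percentages round half away from zero.
* All randomness flows from one top-level seed through documented
  per-stage derived seeds (FNV-1a of a stage label), making every stage
  independently reproducible; written artifacts carry no timestamps so
  reruns are byte-identical.

## Limitations

The comparator cost process and the case year-2/3 intensity paths are
reconstructions from printed ratios and totals, not published
parameters; absolute cohort-level results from confidential claims cannot
be reproduced at desk scale, and the test suite instead verifies the
published arithmetic identities (attributable differences, first-year
shares), estimator/oracle agreement, bootstrap calibration, and the
cohort-construction rules against planted truth.  Indirect costs,
quality-of-life outcomes, currency conversion beyond a constant factor and
propensity-score designs are out of scope.
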