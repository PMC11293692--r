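---
title: "Comparing sign-based and risk-model paediatric triage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing sign-based and risk-model paediatric triage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smarttriage)
```

## The problem

Triage assigns children presenting to an emergency department an acuity
category — *non-urgent* < *priority* < *emergency* — so that the sickest
are seen first. This package implements two approaches side by side and
the machinery to compare them. The first is the WHO ETAT algorithm: a
checklist of clinical signs in which any *emergency* sign (e.g. central
cyanosis, SpO₂ below 90%, the circulation triad, active convulsions)
makes the child an emergency, otherwise any *priority* sign (fever,
trauma, age-banded fast breathing, ...) makes them priority, and a child
without any sign is non-urgent. The second is Smart Triage: a logistic
regression over nine predictors returning a probability of hospital
admission that is cut at a low and a high risk threshold into the same
three categories, supplemented by *independent triggers* — single signs
or vital-sign cut-offs that force at least priority or emergency status
regardless of the model output, so rare catastrophic presentations
cannot be missed by a middling probability.

Because triage has no gold standard, the systems are compared by how
they distribute admissions and deaths across categories: per-category
outcome tables, reclassification (Sankey flow) tables between systems,
and dichotomized diagnostic statistics in which emergency is "test
positive" (high acuity) and priority plus non-urgent are "test negative".

## Rule engines and their reading of the tables

Both rule engines evaluate a fixed vocabulary of 33 boolean signs plus
five vitals (units: months of age, °C, beats and breaths per minute, %
SpO₂, mm MUAC). Deliberate readings, each covered by tests:

* **Threshold strictness.** Comparisons are as printed in the source
  tables: SpO₂ < 90 and the respiratory-rate bands (> 60 / > 50 / > 40
  by age < 2 / 2–11 / ≥ 12 months) are strict; fever is inclusive
  (≥ 37.5 °C). All trigger cut-offs (HR < 45, RR > 60, temperature > 40
  or < 35, MUAC < 115) are strict, so a child at exactly the cut-off
  does not fire.
* **Unknown signs are treated as absent.** A sign that was not elicited
  cannot fire a checklist rule. Validation flags such records with a
  warning so the convention is visible rather than silent. The
  regression predictors are different: a missing categorical predictor
  is an error, because a probability computed from silently imputed
  zeros would be misleading.
* **Obstructed/absent breathing** is excluded from the ETAT emergency
  block by default, mirroring evaluation datasets in which it was not
  collected; `include_obstructed_breathing = TRUE` restores it.
* **The shock composite** is read as cool skin AND (capillary refill
  > 3 s OR weak pulse). The grammar of the printed trigger ("cool hands
  with X or Y") admits a second parenthesization, (cool AND refill) OR
  weak pulse, available behind `shock_rule = "refill_or_pulse"`.
* **Dehydration asymmetry.** ETAT's severe dehydration requires
  diarrhoea plus two of three sub-signs; the Smart Triage dehydration
  trigger requires two of {sunken eyes, slow skin pinch, lethargy} with
  no diarrhoea condition. The engines preserve this asymmetry and the
  test suite pins it on a fixture record.

Both engines return, besides the category, the full list of criteria
that fired (an audit trail), and satisfy a monotonicity property:
setting any single sign, or worsening any vital, never lowers the
category.

## Risk classification and recalibration

`classify_by_risk()` maps a probability *p* to emergency if
*p* ≥ high, priority if low ≤ *p* < high, else non-urgent. The sources
do not state boundary inclusivity; we use "at least this risk"
semantics (closed at the lower edge of each band), documented and
tested. Trigger merging takes the maximum severity of the model
category and the fired triggers, so triggers can only promote — an
invariant asserted over whole cohorts.

Recalibration-in-the-large re-estimates only the intercept on a new
population: `recalibrate_in_the_large()` maximizes the Bernoulli
likelihood of `plogis(lp + δ)` in δ, equivalently solves the score
equation `mean(plogis(lp + δ)) = mean(y)`. Numerics: the score is
strictly increasing in δ, so the solver brackets the root in [−40, 40]
(logit scale; beyond that `plogis` saturates at double precision) and
takes Newton steps that fall back to bisection whenever a step would
leave the bracket, with tolerance 1e−10 on the mean score and a 100
iteration cap. Degenerate outcome vectors (all events or all
non-events) are an explicit error — the MLE would be infinite. Because
only the intercept moves, the ranking of patient probabilities is
unchanged; tests verify both this and agreement with
`glm(y ~ 1 + offset(lp))` to 1e−6. The recalibrated model is used with
its own threshold pair (2.6% / 13% in the shipped spec, versus 8% / 40%
for the original), reflecting threshold choices that accompany intercept
updates in practice.

## The model specification and its placeholder coefficients

`model_spec()` bundles intercept, the nine named coefficients, an SpO₂
transform (identity, affine, or square-root-of-deficit), and the two
thresholds; YAML/JSON round-trip is strict (unknown keys rejected). The
published Smart Triage coefficients are not public in the sources this
package draws on, so the shipped specs carry synthetic placeholder
values: signs chosen for clinical direction (risk increases with
temperature and heart rate, decreases with SpO₂ and MUAC and age),
magnitudes chosen to give a realistic per-unit effect, and an intercept
of −2.58 fixed once so that the mean predicted admission probability on
the default synthetic cohort is the 7% prevalence the generator
targets. The placeholder is labelled non-clinical everywhere it
appears; no packaged result depends on the true coefficients.

## Diagnostic statistics

From a 2×2 table restricted to outcome-known patients, sensitivity =
tp/(tp+fn), specificity = tn/(tn+fp), PPV = tp/(tp+fp), NPV =
tn/(tn+fn); a zero denominator leaves that statistic undefined (NA)
without poisoning the others. Confidence intervals use the
continuity-uncorrected Wilson score method with z = 1.959964. Wilson
was chosen over Clopper–Pearson because it reproduces the published
interval bounds this package's fixtures rebuild — e.g. for 191/395 it
gives 43.5%–53.3% where Clopper–Pearson's lower bound rounds to 43.3% —
and over the Wald interval for its boundary behaviour (it stays inside
[0, 1] and is exact at x = 0 and x = n). One published bound (the lower
NPV limit of the ETAT mortality column) computes to 99.3% by both
Wilson and Clopper–Pearson against a printed 99.2%; we treat that as a
printing artifact and report the computed value. Percentages are
rounded half-away-from-zero to one decimal (`pct1()`), the convention of
clinical tables, rather than R's round-half-even.

The packaged aggregate fixtures (`reference_counts()`) record the
per-category participant, admission and mortality counts of a published
5618-child evaluation (5605 outcome-evaluable after 13 missing
outcomes; 395 admissions; 49 deaths, counting day-of-enrolment,
in-hospital and follow-up deaths together as outcome-positive). Its
participant-characteristics text reports 383 admissions plus 11
readmissions (= 394) while the per-category admission rows sum to 395;
the fixtures follow the per-category table and we document rather than
resolve the discrepancy. Reconstructing 2×2 tables from these counts
reproduces every published point estimate to one decimal place — the
package's core worked example and its acceptance check.

## The synthetic cohort generator

The generator exists so every pipeline stage can be exercised without
patient data. Each child gets: an age drawn from a five-band mixture
(3.2% < 1 month, 29.4% 1–12 months, 55.4% 1–5 years, 10.8% 5–12 years,
1.2% > 12 years — the marginal age structure of the reference cohort);
a standard-normal latent severity *s*; each sign Bernoulli with logit
linear in *s* (nonnegative slopes; injury signs nearly flat); vitals
Gaussian around age-appropriate means shifted adversely in *s*
(SpO₂ and MUAC shift only for *s* > 0, since health does not push them
above normal) and truncated to the validation bounds; and outcomes from
severity-driven logistic laws. The outcome intercepts are calibrated on
the realized severity draws (one-dimensional root solve) so the
*expected* admission and mortality rates equal their targets — 7% and
0.9% by default — exactly, leaving only binomial noise; the in-hospital
share of deaths (31/49 by default) forces admission and the calibration
accounts for the forced group. Deceased children always have a known
outcome; 13/5618 of the rest lose theirs, mirroring the reference
cohort's missingness.

What the generator does *not* emulate: correlations between signs
beyond the shared latent factor, seasonal or site effects, measurement
error structure, and — deliberately — the reference study's per-category
counts and agreement proportions, which depend on the undeposited
per-patient data and the unpublished coefficients. Passing pipeline
tests on synthetic cohorts therefore demonstrates internal coherence
(calibrated marginals, a positive severity–outcome gradient, trigger
monotonicity, determinism), not clinical performance on real children.

## Problem sizes and determinism

The test suite exercises exhaustive sign enumerations (2¹² combinations
against brute-force oracles, plus vital grids straddling every numeric
threshold), 50,000-draw recalibration recoveries (true offsets −1 and
+0.5 recovered within ±0.05), and 50,000-child synthetic cohorts for
marginal-rate and monotonicity properties; smaller cohorts (hundreds to
a few thousand) cover I/O, round-trips and pipeline determinism. All
randomness flows through explicit integer seeds; identical config and
seed give byte-identical CSV/JSON outputs, which the tests assert by
comparing files.

## Limitations

The rule engines implement a specific dataset mapping of ETAT (e.g.
pallor stands in for severe pallor, a single boolean for the skin-pinch
duration); other mappings will classify differently at the margins. The
dichotomized statistics inherit the usual caveat that admission is a
proxy for acuity. The shipped model is a placeholder: conclusions about
Smart Triage performance on real data require the published
coefficients and a real cohort, for which this package supplies the
harness — CSV schema, validation, engines, recalibration and the
evaluation artifacts — but not the data.
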