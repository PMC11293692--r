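# smarttriage

Tools for comparing paediatric emergency-department triage systems in
low-resource settings. The package implements, side by side:

- **ETAT** — the WHO Emergency Triage Assessment and Treatment
  guidelines, a sign-based rule algorithm that assigns children to
  *emergency*, *priority* or *non-urgent* categories from clinical signs
  (central cyanosis, the circulation triad, severe dehydration, fever,
  age-banded fast breathing, ...).
- **Smart Triage** — a nine-predictor logistic regression for the
  probability of hospital admission,
  `p = logit⁻¹(β₀ + Σ βⱼ xⱼ)`, over age, temperature, heart rate,
  transformed oxygen saturation, MUAC, difficulty breathing, pallor,
  oedema and parental concern, mapped to the three categories by dual
  risk thresholds (original 8% / 40%; recalibrated 2.6% / 13%), plus a
  set of **independent emergency and priority triggers** (single signs or
  vital-sign cut-offs such as SpO₂ < 90%, HR < 45 bpm, MUAC < 115 mm)
  that can only raise the model's category, never lower it.
- **Recalibration-in-the-large** — refitting only the model intercept
  `δ` so the mean predicted risk matches the observed admission
  prevalence, by solving the score equation
  `mean(logit⁻¹(lpᵢ + δ)) = ȳ` with a safeguarded Newton iteration.
- An **evaluation layer** — category-by-category reclassification
  (Sankey flow) tables, per-category outcome tables, and dichotomized
  (high acuity = emergency vs low acuity = priority + non-urgent)
  sensitivity / specificity / PPV / NPV with Wilson score 95% CIs.
- A **synthetic cohort generator** that emulates the marginal structure
  of a published two-hospital Kenyan evaluation cohort (age mixture, 7%
  admission, 0.9% mortality) through a latent-severity model, so the
  whole pipeline is testable without patient data.

The intended audience is researchers evaluating triage systems: the
package reproduces the published aggregate diagnostic tables from count
fixtures alone, and lets you rerun the entire comparison on your own
cohort CSV or on synthetic data.

All user-facing functions take a data frame first and return tibbles, so
the pieces chain with the pipe; results carry `tidy()`, `glance()` and
`autoplot()` methods.

**The shipped model coefficients are placeholders.** The published Smart
Triage coefficients are not distributed here; the packaged specs
(`example_model_spec()`) are synthetic, directionally sensible values for
use with the synthetic cohort only, and must never be used clinically.
Users holding the published model can load it via `read_model_spec()`.

## Worked example

Reconstructing a published diagnostic table from its 2×2 counts (191
admitted children triaged as emergencies, 322 non-admitted emergencies,
204 admitted non-emergencies, 4888 neither):

```r
library(smarttriage)
diagnostic_summary(191, 322, 204, 4888)
#> <diagnostic_summary> tp=191 fp=322 fn=204 tn=4888 (n=5605)
#>   sensitivity 48.4% (43.5% - 53.3%)  [191/395]
#>   specificity 93.8% (93.1% - 94.4%)  [4888/5210]
#>   ppv         37.2% (33.2% - 41.5%)  [191/513]
#>   npv         96.0% (95.4% - 96.5%)  [4888/5092]
```

ETAT found 48.4% of the children who ended up admitted (sensitivity),
while 96.0% of those it sent to the low-acuity queue were indeed not
admitted (NPV). Running the full pipeline on a synthetic cohort:

```r
co  <- generate_cohort(synthetic_cohort_config(n = 1000, seed = 1))
asg <- triage_cohort(co, example_model_spec("original"),
                     example_model_spec("recalibrated"))
dat <- dplyr::inner_join(asg, co[, c("patient_id", "admitted", "died",
                                     "outcome_known")], by = "patient_id")
transition_table(dat, etat, st_with_triggers)
#> <transition_table> etat -> st_with_triggers (n = 1000, agreement 73.3%)
#>             to
#> from         non-urgent priority emergency
#>   non-urgent        454       73         5
#>   priority          119      239        32
#>   emergency           9       29        40
```

733 of 1000 synthetic children keep their category when moving from ETAT
to the Smart Triage model with triggers; the off-diagonal cells are the
reclassification flows a Sankey diagram draws (`autoplot()` renders one;
`write_sankey_json()` exports the flow list). `run_simulate()`,
`run_triage()`, `run_evaluate()` and `run_recalibrate()` wire these
stages into a file-based pipeline, also reachable from a shell via
`inst/cli/smarttriage.R` (subcommands `simulate`, `triage`, `evaluate`,
`recalibrate`, `reproduce-tables`).

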