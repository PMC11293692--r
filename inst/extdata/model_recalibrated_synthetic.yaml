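# PLACEHOLDER, NON-CLINICAL Smart Triage model specification.
# Coefficients are synthetic: directionally sensible magnitudes chosen for
# use with the package's synthetic cohort generator. They are NOT the
# published Smart Triage coefficients and must never be used for patient
# care. Users holding the published model can drop it into this schema.
# The intercept here equals the original placeholder's; refit it for a
# target population with recalibrate_model_spec() (recalibration in the
# large) before using these lower thresholds.
label: synthetic-placeholder (recalibrated thresholds)
intercept: -2.58
coefficients:
  age: -0.006            # per month
  temperature: 0.45      # per degC
  heart_rate: 0.015      # per bpm
  spo2_transformed: -0.18 # per % (identity transform)
  muac: -0.012           # per mm
  difficulty_breathing: 1.1
  pallor: 0.7
  oedema: 0.9
  parental_concern: 0.5
spo2_transform:
  name: identity
  params: {}
low_threshold: 0.026
high_threshold: 0.13
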