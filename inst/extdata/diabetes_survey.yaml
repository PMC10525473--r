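# Summary statistics of a 5-year type 2 diabetes incidence survey
# (China Cardio Metabolic Disease and Cancer Cohort), as published:
# per-age-group patient counts, sex counts, and outcome subgroup sizes.
#
# The survey publishes subgroup counts directly; per-factor hazard ratios,
# exposure prevalences and the age-group mean/SD ages are NOT reprinted
# here.  The values below marked user_supplied: false are documented
# synthetic placeholders in plausible epidemiological ranges (HR 1.5-3.0,
# prevalence 0.2-0.5); replace them with the survey's published values
# before drawing substantive conclusions.
schema_version: 1
age_divisor: 100
balanced_minority_target: 84692
seeds:
  generation: 101
  shuffle: 202
  split: 46
  network: 303
metadata:
  user_supplied:
    counts: true
    age_moments: false
    hazard_ratios: false
    prevalences: false
age_groups:
  - label: "40-<55"
    lower_bound: 40
    upper_bound: 55
    mean_age: 47.2
    sd_age: 4.2
    n_healthy: 42825
    n_diabetic: 2306
    n_male: 13178
    n_female: 31953
  - label: "55-<65"
    lower_bound: 55
    upper_bound: 65
    mean_age: 59.6
    sd_age: 2.9
    n_healthy: 31355
    n_diabetic: 2478
    n_male: 11638
    n_female: 22195
  - label: "65-<75"
    lower_bound: 65
    upper_bound: 75
    mean_age: 69.3
    sd_age: 2.8
    n_healthy: 11570
    n_diabetic: 1176
    n_male: 5250
    n_female: 7496
  - label: ">=75"
    lower_bound: 75
    upper_bound: 100
    mean_age: 78.6
    sd_age: 3.3
    n_healthy: 1851
    n_diabetic: 203
    n_male: 882
    n_female: 1172
risk_factors:
  - name: diet
    hazard_ratio_by_group:
      "40-<55": 1.9
      "55-<65": 1.8
      "65-<75": 1.7
      ">=75": 1.6
    prevalence_by_group:
      "40-<55": 0.30
      "55-<65": 0.30
      "65-<75": 0.28
      ">=75": 0.25
  - name: inactivity
    hazard_ratio_by_group:
      "40-<55": 2.0
      "55-<65": 1.9
      "65-<75": 1.8
      ">=75": 1.7
    prevalence_by_group:
      "40-<55": 0.25
      "55-<65": 0.30
      "65-<75": 0.35
      ">=75": 0.40
  - name: alcohol
    hazard_ratio_by_group:
      "40-<55": 1.5
      "55-<65": 1.5
      "65-<75": 1.5
      ">=75": 1.5
    prevalence_by_group:
      "40-<55": 0.30
      "55-<65": 0.28
      "65-<75": 0.25
      ">=75": 0.20
  - name: sleep
    hazard_ratio_by_group:
      "40-<55": 1.7
      "55-<65": 1.7
      "65-<75": 1.6
      ">=75": 1.6
    prevalence_by_group:
      "40-<55": 0.25
      "55-<65": 0.28
      "65-<75": 0.30
      ">=75": 0.32
  - name: obesity
    hazard_ratio_by_group:
      "40-<55": 2.8
      "55-<65": 2.6
      "65-<75": 2.4
      ">=75": 2.2
    prevalence_by_group:
      "40-<55": 0.35
      "55-<65": 0.38
      "65-<75": 0.40
      ">=75": 0.38
  - name: hypertension
    hazard_ratio_by_group:
      "40-<55": 2.5
      "55-<65": 2.3
      "65-<75": 2.1
      ">=75": 1.9
    prevalence_by_group:
      "40-<55": 0.25
      "55-<65": 0.35
      "65-<75": 0.45
      ">=75": 0.50
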