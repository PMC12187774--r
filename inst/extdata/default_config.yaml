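# Example configuration: synthetic cohort at the scale of a single-center
# cystectomy database plus a desk-scale evaluation profile.
synthetic:
  n_patients: 1482
  base_rate_beneficial: 0.783
  tifb_ne_coupling: -0.02
  noise_sd: 0.02
  seed: 1
  covariate_spec:
    age:           {type: continuous, mean: 68.5, sd: 10.5}
    bmi:           {type: continuous, mean: 25.8, sd: 4.3}
    asa:           {type: ordinal, probs: [0.021, 0.494, 0.460, 0.025]}
    ckd_stage:     {type: ordinal, probs: [0.284, 0.410, 0.260, 0.036, 0.010]}
    copd:          {type: binary, prevalence: 0.201}
    heart_disease: {type: binary, prevalence: 0.312}
    hypertension:  {type: binary, prevalence: 0.510}
    statins:       {type: binary, prevalence: 0.233}
    neoadj_chemo:  {type: binary, prevalence: 0.155}
    year:          {type: continuous, mean: 2010.5, sd: 5.5}
  confounding_coefs:
    "(Intercept)": -0.28
    year: -1.10
    ckd_stage: 0.25
    heart_disease: -0.35
    hypertension: -0.30
  outcome_coefs:
    age: -0.25
    bmi: -0.30
    asa: -0.25
    ckd_stage: -0.30
    heart_disease: -0.30
    hypertension: -0.45
    statins: -0.20
    year: -0.15
  effect_coefs:
    "(Intercept)": 0.72
    hypertension: 0.45
    heart_disease: 0.40
    age: 0.30
    ckd_stage: 0.25
treatment:
  slope: 0.02
  offset: -0.04
  offset_grid: [-0.12, -0.08, -0.04, 0.0, 0.04, 0.08]
  adjustment_set: [year, ckd_stage, heart_disease, hypertension]
  multiplier: 10000
  clip_epsilon: 0.01
learners:
  logistic:
    kind: logistic_regression
  random_forest:
    kind: random_forest
    hyperparameters:
      ntree: 500
experiment:
  n_bootstrap: 20
  n_pseudo_samples: 2
  n_cv_splits: 2
  train_fraction: 0.6
  master_seed: 1
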