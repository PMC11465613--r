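{
  "name": "ADRS",
  "form": "logistic",
  "hypertension_definition": "clinical",
  "intercept": -9.6,
  "probability_link": {"type": "direct_logistic"},
  "provisional": true,
  "source": "African Diabetes Risk Score (Mayige, developed in Tanzanian/Senegalese/Guinean cohorts). The original coefficients are unpublished; this file is a PROVISIONAL synthetic reconstruction matching the published description of the model (age, waist circumference and hypertensive status as predictors, logistic form). Replace with transcribed coefficients when the primary specification becomes available.",
  "items": [
    {"predictor": "age", "kind": "linear_coefficient", "coefficient": 0.045},
    {"predictor": "waist_circumference", "kind": "linear_coefficient", "coefficient": 0.04},
    {"predictor": "hypertension", "kind": "categorical_points", "levels": {"yes": 0.6, "no": 0}}
  ]
}
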