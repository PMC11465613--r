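{
  "name": "ADA",
  "form": "points",
  "hypertension_definition": "clinical",
  "probability_link": {"type": "score_logistic", "a": -1.8, "b": 0.45},
  "provisional": true,
  "source": "American Diabetes Association risk test (Bang et al. 2009, developed in a multi-ethnic US population). Six items: age, sex, family history, hypertension, BMI, physical activity (gestational-diabetes item omitted; not collected in this cohort dialect). Point values and the score-to-probability link transcribed PROVISIONALLY from the source; physical_activity category 1 denotes the lowest (inactive) category.",
  "items": [
    {"predictor": "age", "kind": "categorical_points", "cut_points": [40, 50, 60], "values": [0, 1, 2, 3]},
    {"predictor": "sex", "kind": "categorical_points", "levels": {"male": 1, "female": 0}},
    {"predictor": "family_history_dm", "kind": "categorical_points", "levels": {"yes": 1, "no": 0}},
    {"predictor": "hypertension", "kind": "categorical_points", "levels": {"yes": 1, "no": 0}},
    {"predictor": "bmi", "kind": "categorical_points", "cut_points": [25, 30, 40], "values": [0, 1, 2, 3]},
    {"predictor": "physical_activity", "kind": "categorical_points", "levels": {"1": 1, "2": 0, "3": 0}}
  ]
}
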