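{
  "name": "IRS",
  "form": "points",
  "hypertension_definition": "clinical",
  "probability_link": {"type": "score_logistic", "a": -4.0, "b": 0.035},
  "provisional": true,
  "source": "Indian Diabetes Risk Score (Mohan et al., MDRF-IDRS, developed in an Indian population). Four items: age, waist circumference, physical activity, family history; hypertension is not included. Point values transcribed PROVISIONALLY from the source (score range 0-100); physical_activity categories 1-3 map sedentary/moderate/vigorous. The score-to-probability link (a, b) is a provisional logistic fit to the source's risk-per-score-band data.",
  "items": [
    {"predictor": "age", "kind": "categorical_points", "cut_points": [35, 50], "values": [0, 20, 30]},
    {"predictor": "waist_circumference", "kind": "categorical_points",
     "cut_points": [90, 100], "values": [0, 10, 20],
     "sex_specific": {"female": {"cut_points": [80, 90]}}},
    {"predictor": "physical_activity", "kind": "categorical_points", "levels": {"1": 20, "2": 10, "3": 0}},
    {"predictor": "family_history_dm", "kind": "categorical_points", "levels": {"yes": 10, "no": 0}}
  ]
}
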