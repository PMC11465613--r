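{
  "name": "SIMPLIFIED_FINDRISC",
  "form": "points",
  "hypertension_definition": "medication_only",
  "probability_link": {"type": "score_logistic", "a": -5.5, "b": 0.28},
  "provisional": true,
  "source": "Simplified Finnish Diabetes Risk Score (Bergmann et al. 2007, derived from Lindstrom & Tuomilehto 2003 FINDRISC by dropping the physical-activity and diet items). Point values transcribed PROVISIONALLY from the FINDRISC point table; hypertension enters only as use of blood-pressure medication, as in the source. The score-to-probability link (a, b) is a provisional logistic fit to the source's published risk-per-score-band table.",
  "items": [
    {"predictor": "age", "kind": "categorical_points", "cut_points": [45, 55, 65], "values": [0, 2, 3, 4]},
    {"predictor": "bmi", "kind": "categorical_points", "cut_points": [25, 30], "values": [0, 1, 3]},
    {"predictor": "waist_circumference", "kind": "categorical_points",
     "cut_points": [94, 102], "values": [0, 3, 4],
     "sex_specific": {"female": {"cut_points": [80, 88]}}},
    {"predictor": "hypertension", "kind": "categorical_points", "levels": {"yes": 2, "no": 0}},
    {"predictor": "family_history_dm", "kind": "categorical_points", "levels": {"yes": 5, "no": 0}}
  ]
}
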