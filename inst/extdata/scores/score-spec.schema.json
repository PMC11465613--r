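{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "t2dval score specification",
  "type": "object",
  "required": ["name", "form", "items"],
  "properties": {
    "name": {"type": "string"},
    "form": {"enum": ["points", "logistic"]},
    "intercept": {"type": "number", "description": "Required when form is 'logistic'."},
    "hypertension_definition": {"enum": ["clinical", "medication_only"], "default": "clinical"},
    "provisional": {"type": "boolean"},
    "source": {"type": "string"},
    "probability_link": {
      "type": "object",
      "required": ["type"],
      "properties": {
        "type": {"enum": ["direct_logistic", "score_logistic"]},
        "a": {"type": "number"},
        "b": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "items": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["predictor", "kind"],
        "properties": {
          "predictor": {
            "enum": ["age", "sex", "waist_circumference", "bmi", "systolic_bp",
                     "diastolic_bp", "bp_medication", "hypertension",
                     "family_history_dm", "physical_activity", "residency"]
          },
          "kind": {"enum": ["categorical_points", "threshold_points", "linear_coefficient"]},
          "cut_points": {
            "type": "array", "items": {"type": "number"},
            "description": "Strictly increasing; intervals are lower-inclusive half-open [lo, hi)."
          },
          "values": {
            "type": "array", "items": {"type": "number"},
            "description": "One value per interval: length(cut_points) + 1."
          },
          "levels": {
            "type": "object", "additionalProperties": {"type": "number"},
            "description": "Alternative to cut_points for discrete predictors."
          },
          "cut_point": {"type": "number"},
          "coefficient": {"type": "number"},
          "sex_specific": {
            "type": "object",
            "properties": {
              "male": {"type": "object", "properties": {"cut_points": {"type": "array"}}},
              "female": {"type": "object", "properties": {"cut_points": {"type": "array"}}}
            }
          }
        }
      }
    }
  }
}
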