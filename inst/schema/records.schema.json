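{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Intake record set",
  "description": "Hierarchical two-method dietary records: household -> participant -> recording period day -> eating occasion -> serving. Amounts are grams of edible portion; a serving amount is either a bare non-negative number or an analyst estimate set awaiting reconciliation.",
  "type": "object",
  "required": ["households"],
  "properties": {
    "households": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["household_id", "site", "participants"],
        "properties": {
          "household_id": {"type": "string"},
          "site": {"enum": ["rural", "semirural", "urban"]},
          "participants": {
            "type": "array",
            "description": "Exactly one mother, at most one child.",
            "items": {
              "type": "object",
              "required": ["participant_id", "role"],
              "properties": {
                "participant_id": {"type": "string"},
                "role": {"enum": ["mother", "child"]}
              }
            }
          },
          "recipes": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["recipe_id", "ingredients"],
              "properties": {
                "recipe_id": {"type": "string"},
                "ingredients": {
                  "type": "array",
                  "minItems": 1,
                  "items": {
                    "type": "object",
                    "required": ["food_id", "grams"],
                    "properties": {
                      "food_id": {"type": "string"},
                      "grams": {"type": "number", "exclusiveMinimum": 0},
                      "cooking_method": {"type": "string"}
                    }
                  }
                },
                "final_weight": {"type": "number", "exclusiveMinimum": 0}
              }
            }
          },
          "days": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["period", "day_index", "occasions"],
              "properties": {
                "period": {"enum": ["ivfr1", "recall", "ivfr2"]},
                "day_index": {"enum": [1, 2, 3]},
                "is_weekend": {"type": "boolean"},
                "training": {
                  "type": "boolean",
                  "description": "Supervised practice day; always excluded from analysis."
                },
                "occasions": {
                  "type": "array",
                  "items": {
                    "type": "object",
                    "required": ["servings"],
                    "properties": {
                      "occasion_id": {"type": "string"},
                      "servings": {
                        "type": "array",
                        "minItems": 1,
                        "items": {"$ref": "#/$defs/serving"}
                      }
                    }
                  }
                }
              }
            }
          }
        }
      }
    }
  },
  "$defs": {
    "amount": {
      "oneOf": [
        {"type": "number", "minimum": 0},
        {
          "type": "object",
          "required": ["estimates"],
          "properties": {
            "estimates": {
              "type": "array",
              "minItems": 1,
              "maxItems": 3,
              "items": {
                "type": "object",
                "required": ["analyst_id", "grams"],
                "properties": {
                  "analyst_id": {"type": "string"},
                  "grams": {"type": "number", "exclusiveMinimum": 0}
                }
              }
            },
            "third": {
              "type": "number",
              "exclusiveMinimum": 0,
              "description": "Final decision by a reviewing third analyst when the two blinded estimates differ by more than the tolerance."
            }
          }
        }
      ]
    },
    "serving": {
      "type": "object",
      "required": ["serving_type", "item_ref", "served", "eaters"],
      "properties": {
        "serving_type": {"enum": ["own", "shared"]},
        "item_kind": {"enum": ["food", "recipe"], "default": "food"},
        "item_ref": {"type": "string"},
        "served": {"$ref": "#/$defs/amount"},
        "leftover": {"$ref": "#/$defs/amount"},
        "consumption_status": {
          "enum": ["eaten_completely", "not_consumed", "partial"],
          "default": "partial"
        },
        "eaters": {
          "type": "object",
          "description": "Own-plate servings list exactly one participant and no nonparticipants.",
          "properties": {
            "participant_ids": {"type": "array", "items": {"type": "string"}},
            "n_nonparticipant_adults": {"type": "integer", "minimum": 0},
            "n_nonparticipant_children": {"type": "integer", "minimum": 0}
          }
        }
      }
    }
  }
}
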