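{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Haemophilia monitoring instrument configuration",
  "type": "object",
  "required": ["disease", "setting", "domains"],
  "properties": {
    "disease": { "enum": ["A", "B"] },
    "setting": { "enum": ["prophylaxis", "on_demand"] },
    "provenance": { "type": "string" },
    "domains": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["id", "name", "weight_pct", "items"],
        "properties": {
          "id": { "type": "string" },
          "name": {
            "enum": ["pharmacokinetics", "bleeding_episodes", "joint_health", "adherence_qol"]
          },
          "weight_pct": { "type": "number", "minimum": 0, "maximum": 100 },
          "items": {
            "type": "array",
            "minItems": 1,
            "items": {
              "type": "object",
              "required": ["id", "text", "scale_size", "weight_pct", "options"],
              "properties": {
                "id": { "type": "string" },
                "text": { "type": "string" },
                "scale_size": { "enum": [3, 4] },
                "weight_pct": { "type": "number", "exclusiveMinimum": 0, "maximum": 100 },
                "bucketing_rule": {
                  "enum": ["abr", "ajbr", "pj_count", "tj_count", "pj_trend",
                           "tj_trend", "hjhs_delta", "headus_delta", "adherence",
                           "lss_current", "lss_change", "trough_satisfaction"]
                },
                "options": {
                  "type": "array",
                  "minItems": 3,
                  "maxItems": 4,
                  "items": {
                    "type": "object",
                    "required": ["label", "severity_rank", "value"],
                    "properties": {
                      "label": { "type": "string" },
                      "severity_rank": { "type": "integer", "minimum": 0 },
                      "value": { "type": "number", "minimum": 0, "maximum": 1 }
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
  "description": "Domain weights must sum to 100 across domains and item weights to 100 within each domain; within an item, severity ranks are 0..k-1 with no gaps and the standardised value is 0 at rank 0, 1 at the highest rank, and non-decreasing in rank. On-demand configurations contain no pharmacokinetics domain."
}
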