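{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "growthref synthetic cohort specification",
  "type": "object",
  "required": ["n_subjects", "parameters", "seed"],
  "properties": {
    "n_subjects": { "type": "integer", "minimum": 1 },
    "parameters": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["parameter", "ga_min", "ga_max", "n_records", "noise_sd"],
        "properties": {
          "parameter": { "enum": ["AC", "CRL", "EFW", "HC", "BPD", "FL"] },
          "units": { "enum": ["cm", "g"] },
          "ga_min": { "type": "integer", "minimum": 1 },
          "ga_max": { "type": "integer", "minimum": 2 },
          "n_records": { "type": "integer", "minimum": 1 },
          "noise_sd": { "type": "number", "minimum": 0 }
        }
      }
    },
    "subject_effect_sd": { "type": "number", "minimum": 0 },
    "gdm_prevalence": { "type": "number", "minimum": 0, "maximum": 1 },
    "pe_prevalence": { "type": "number", "minimum": 0, "maximum": 1 },
    "gdm_effect": { "type": "number", "minimum": 0 },
    "pe_effect": { "type": "number", "maximum": 0 },
    "noise_sd_slope": { "type": "number" },
    "seed": { "type": "integer" },
    "coefficients": {
      "type": "object",
      "description": "ascending polynomial coefficients per parameter",
      "additionalProperties": {
        "type": "array",
        "items": { "type": "number" }
      }
    }
  }
}
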