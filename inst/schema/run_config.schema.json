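{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "growthref run configuration",
  "type": "object",
  "additionalProperties": false,
  "properties": {
    "input": {
      "type": ["string", "null"],
      "description": "Path to a records CSV; null generates a default synthetic cohort"
    },
    "parameters": {
      "type": "array",
      "items": { "enum": ["AC", "CRL", "EFW", "HC", "BPD", "FL"] },
      "minItems": 1
    },
    "degree_policy": { "enum": ["fixed", "auto"] },
    "degree": { "type": "integer", "minimum": 1, "maximum": 3 },
    "lambda_policy": { "enum": ["fixed", "grid"] },
    "lambda": { "type": "number", "minimum": 0 },
    "lambda_grid": {
      "type": "array",
      "items": { "type": "number", "minimum": 0 }
    },
    "split_ratio": { "type": "number", "exclusiveMinimum": 0, "exclusiveMaximum": 1 },
    "k_folds": { "type": "integer", "minimum": 2 },
    "band_mode": { "enum": ["coefficient", "rmse"] },
    "degree_epsilon": { "type": "number", "minimum": 0 },
    "seed": { "type": "integer" },
    "n_subjects": { "type": "integer", "minimum": 1 }
  }
}
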