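{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "ORG model fit report",
  "type": "object",
  "required": ["model_id", "params", "ci_low", "ci_high", "r_squared",
               "rms_nm", "rms_late_nm", "flags", "n_points"],
  "properties": {
    "model_id": {"type": "string"},
    "params": {"type": "object", "additionalProperties": {"type": "number"}},
    "ci_low": {"type": "object",
               "additionalProperties": {"type": ["number", "null"]}},
    "ci_high": {"type": "object",
                "additionalProperties": {"type": ["number", "null"]}},
    "r_squared": {"type": ["number", "null"]},
    "rms_nm": {"type": "number", "minimum": 0},
    "rms_late_nm": {"type": ["number", "null"]},
    "flags": {
      "type": "object",
      "required": ["converged", "degenerate"],
      "properties": {
        "converged": {"type": "boolean"},
        "degenerate": {"type": "boolean"},
        "reliable": {"type": "object",
                     "additionalProperties": {"type": "boolean"}}
      }
    },
    "n_points": {"type": "integer", "minimum": 1},
    "weights_applied": {"type": "string"}
  }
}
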