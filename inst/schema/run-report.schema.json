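{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "sidesearch run report",
  "type": "object",
  "required": ["outcome", "measure", "n", "offset_D", "overall", "subgroups",
               "config", "seed", "version"],
  "properties": {
    "outcome": {"type": "string"},
    "measure": {"type": "string", "enum": ["continuous", "binary"]},
    "n": {"type": "integer"},
    "offset_D": {"type": "number"},
    "overall": {
      "type": "object",
      "required": ["diff", "se", "ci_low", "ci_high", "n1", "n2"],
      "properties": {
        "diff": {"type": "number"},
        "se": {"type": "number"},
        "ci_low": {"type": "number"},
        "ci_high": {"type": "number"},
        "summary1": {"type": "number"},
        "summary2": {"type": "number"},
        "n1": {"type": "integer"},
        "n2": {"type": "integer"}
      }
    },
    "subgroups": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["rule", "depth", "n1", "n2", "diff", "ci_low",
                     "ci_high", "adjusted_p"],
        "properties": {
          "rule": {"type": "string"},
          "depth": {"type": "integer"},
          "n1": {"type": "number"},
          "n2": {"type": "number"},
          "summary1": {"type": "number"},
          "summary2": {"type": "number"},
          "diff": {"type": "number"},
          "se": {"type": "number"},
          "ci_low": {"type": "number"},
          "ci_high": {"type": "number"},
          "p_split": {"type": "number"},
          "adjusted_p": {"type": "number"}
        }
      }
    },
    "config": {
      "type": "object",
      "required": ["M", "L", "gamma", "min_node", "alpha", "B"],
      "properties": {
        "M": {"type": "integer"},
        "L": {"type": "integer"},
        "gamma": {"type": "array"},
        "min_node": {"type": "number"},
        "min_events": {"type": "number"},
        "alpha": {"type": "number"},
        "B": {"type": "integer"}
      }
    },
    "seed": {"type": "integer"},
    "version": {"type": "string"}
  }
}
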