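{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "ClarID codebook",
  "type": "object",
  "required": ["biosample", "subject"],
  "additionalProperties": true,
  "properties": {
    "biosample": {
      "type": "object",
      "required": ["project", "species", "tissue", "sample_type", "assay", "timepoint"],
      "patternProperties": {
        "^[A-Za-z_][A-Za-z0-9_]*$": {"$ref": "#/$defs/component"}
      }
    },
    "subject": {
      "type": "object",
      "required": ["type", "sex", "age_group"],
      "patternProperties": {
        "^[A-Za-z_][A-Za-z0-9_]*$": {"$ref": "#/$defs/component"}
      }
    },
    "rules": {
      "type": "object",
      "patternProperties": {
        "^[A-Za-z_][A-Za-z0-9_]*$": {"type": "string", "minLength": 1}
      }
    }
  },
  "$defs": {
    "component": {
      "type": "object",
      "patternProperties": {
        "^.+$": {
          "type": "object",
          "required": ["code", "stub_code"],
          "properties": {
            "code": {"type": "string", "minLength": 1, "pattern": "^[A-Za-z0-9_.]+$"},
            "stub_code": {"type": "string", "minLength": 1, "pattern": "^[A-Za-z0-9]+$"},
            "label": {"type": "string"},
            "id": {"type": "string", "pattern": "^[A-Za-z][A-Za-z0-9_.]*:[^ ]+$"},
            "tax_code": {"type": "string", "pattern": "^[A-Z]{3}$"}
          }
        }
      }
    }
  }
}
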