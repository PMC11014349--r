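{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "mirmimic template registry",
  "type": "object",
  "required": ["version", "mirnas", "templates"],
  "properties": {
    "version": {"type": "integer"},
    "description": {"type": "string"},
    "mirnas": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["guide"],
        "properties": {"guide": {"type": "string", "pattern": "^[ACGU]+$"}}
      }
    },
    "templates": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "mirna", "guide_rules", "passenger_rules",
                     "mismatch_spec", "architecture", "shortlisted", "provenance"],
        "properties": {
          "id": {"type": "string"},
          "mirna": {"type": "string"},
          "guide_rules": {"type": "array", "items": {"$ref": "#/$defs/rule"}},
          "passenger_rules": {"type": "array", "items": {"$ref": "#/$defs/rule"}},
          "mismatch_spec": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["position", "kind"],
              "properties": {
                "position": {"type": "integer", "minimum": 1},
                "kind": {"enum": ["SUBSTITUTION", "DELETION"]},
                "base": {"enum": ["A", "C", "G", "U", "T"]}
              }
            }
          },
          "architecture": {
            "enum": ["BLUNT_SYMMETRIC", "OVERHANG_3P", "ASYMMETRIC", "NICKED", "HAIRPIN"]
          },
          "shortlisted": {"type": "boolean"},
          "provenance": {"type": "string"}
        }
      }
    }
  },
  "$defs": {
    "sugar": {"enum": ["RIBO", "OME", "FLU", "DEOXY"]},
    "rule": {
      "type": "object",
      "required": ["tag"],
      "properties": {
        "tag": {
          "enum": ["ALTERNATING", "BASE_CLASS", "POSITIONAL", "TERMINAL_PS",
                   "POSITIONAL_PS", "OVERHANG", "PASSENGER_LENGTH", "HAIRPIN",
                   "NICK", "FIVE_PRIME_PHOSPHATE"]
        },
        "first_sugar": {"$ref": "#/$defs/sugar"},
        "second_sugar": {"$ref": "#/$defs/sugar"},
        "phase": {"enum": [0, 1]},
        "base_class": {"enum": ["PYRIMIDINE", "PURINE"]},
        "sugar": {"$ref": "#/$defs/sugar"},
        "positions": {"type": "array", "items": {"type": "integer", "minimum": 1}},
        "n_5prime": {"type": "integer", "minimum": 0},
        "n_3prime": {"type": "integer", "minimum": 0},
        "sequence": {"type": "string", "pattern": "^[ACGU]+$"},
        "count": {"type": "integer", "minimum": 1},
        "anchor": {"enum": ["GUIDE_3P"]},
        "loop": {"type": "string", "pattern": "^[ACGU]+$"},
        "split": {"type": "integer", "minimum": 1}
      }
    }
  }
}
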