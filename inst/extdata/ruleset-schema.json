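{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "crsbiologic rule-set document",
  "type": "object",
  "required": ["name", "tree"],
  "properties": {
    "name": {"type": "string"},
    "thresholds": {"type": "object", "additionalProperties": {"type": "number"}},
    "report_ids": {"type": "array", "items": {"type": "string"}},
    "sections": {"type": "object", "additionalProperties": {"type": "string"}},
    "tree": {"$ref": "#/$defs/node"}
  },
  "$defs": {
    "node": {
      "type": "object",
      "required": ["kind", "id"],
      "properties": {
        "kind": {"enum": ["threshold", "flag", "all", "any", "at_least"]},
        "id": {"type": "string"},
        "label": {"type": "string"},
        "field": {"type": "string"},
        "cutoff": {"type": "number"},
        "k": {"type": "integer", "minimum": 1},
        "children": {"type": "array", "items": {"$ref": "#/$defs/node"}, "minItems": 1}
      },
      "allOf": [
        {"if": {"properties": {"kind": {"const": "threshold"}}},
         "then": {"required": ["field", "cutoff"]}},
        {"if": {"properties": {"kind": {"const": "flag"}}},
         "then": {"required": ["field"]}},
        {"if": {"properties": {"kind": {"enum": ["all", "any"]}}},
         "then": {"required": ["children"]}},
        {"if": {"properties": {"kind": {"const": "at_least"}}},
         "then": {"required": ["k", "children"]}}
      ]
    }
  }
}
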