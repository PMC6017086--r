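{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "geomroute/cycle_result/1.0",
  "title": "geomroute cycle result",
  "type": "object",
  "required": ["schema_version", "dg_bind_kcal_mol", "keq_A3", "v0_A3",
               "temperature_K", "contributions"],
  "properties": {
    "schema_version": {"type": "string"},
    "dg_bind_kcal_mol": {"type": "number"},
    "error_kcal_mol": {"type": ["number", "null"]},
    "keq_A3": {"type": "number"},
    "v0_A3": {"type": "number"},
    "temperature_K": {"type": "number"},
    "time_ns": {"type": ["number", "null"]},
    "seed": {"type": ["integer", "null"]},
    "contributions": {
      "type": "array",
      "minItems": 9,
      "maxItems": 9,
      "items": {
        "type": "object",
        "required": ["name", "dg_kcal_mol"],
        "properties": {
          "name": {"type": "string"},
          "dg_kcal_mol": {"type": "number"},
          "error_kcal_mol": {"type": ["number", "null"]},
          "time_ns": {"type": ["number", "null"]}
        }
      }
    }
  }
}
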