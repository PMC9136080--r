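{
  "component": "vanillic acid",
  "mw": 168.15,
  "herbs": [
    {"code": "CX", "grams": 50, "mg_per_g": 0.08}
  ],
  "anchor": {
    "species": "mouse",
    "dose_mg_per_kg": 30.00,
    "brain_level": 30.00,
    "brain_level_unit": "ug/g",
    "route": "injection"
  },
  "body_weight_kg": 70
}
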