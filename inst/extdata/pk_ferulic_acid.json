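{
  "component": "ferulic acid",
  "mw": 194.18,
  "herbs": [
    {"code": "CX", "grams": 50, "mg_per_g": 0.19},
    {"code": "RS", "grams": 50, "mg_per_g": 32.70}
  ],
  "anchor": {
    "species": "rat",
    "dose_mg_per_kg": 63.75,
    "brain_level": 120.01,
    "brain_level_unit": "ng/g",
    "route": "oral"
  },
  "body_weight_kg": 70
}
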