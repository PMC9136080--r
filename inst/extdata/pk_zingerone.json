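{
  "component": "zingerone",
  "mw": 194.23,
  "herbs": [
    {"code": "SJ", "grams": 250, "mg_per_g": 27.30}
  ],
  "anchor": {
    "species": "rat",
    "dose_mg_per_kg": 10.90,
    "brain_level": 45.00,
    "brain_level_unit": "ng/g",
    "route": "oral"
  },
  "body_weight_kg": 70
}
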