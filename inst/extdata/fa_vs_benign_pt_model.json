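{
  "name": "fa_vs_benign_pt",
  "intercept": -197.039,
  "coefficients": {
    "area_um2": -3.881,
    "min_caliper_um": 35.176,
    "eccentricity": 172.063
  },
  "cutoff": -1.0596,
  "labels": ["benign PT-like", "FA-like"]
}
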