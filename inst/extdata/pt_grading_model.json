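{
  "name": "pt_grading",
  "intercept": 108.227,
  "coefficients": {
    "perimeter_um": 2.381,
    "circularity": -20.392,
    "min_caliper_um": -10.810,
    "eccentricity": -123.711
  },
  "cutoff": -0.2008,
  "labels": ["benign-like", "borderline/malignant-like"]
}
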