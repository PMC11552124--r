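{
  "name": "circularity_recurrence",
  "intercept": 0,
  "coefficients": {
    "circularity": 1
  },
  "cutoff": 0.698,
  "labels": ["low circularity", "high circularity"]
}
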