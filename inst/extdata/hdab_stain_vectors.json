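{
  "hematoxylin": [0.65, 0.70, 0.29],
  "dab": [0.27, 0.57, 0.78],
  "I0": 255
}
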