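[
  {"min_n": 3, "points": 0.15},
  {"min_n": 5, "points": 0.30},
  {"min_n": 7, "points": 0.45}
]
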