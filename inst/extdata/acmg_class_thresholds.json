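[
  {"min_score": 0.99, "label": "Pathogenic", "class": 5},
  {"min_score": 0.90, "label": "Likely pathogenic", "class": 4},
  {"min_score": -0.89, "label": "Uncertain significance", "class": 3},
  {"min_score": -0.98, "label": "Likely benign", "class": 2},
  {"min_score": -1e9, "label": "Benign", "class": 1}
]
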