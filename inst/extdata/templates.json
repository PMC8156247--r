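[
  {
    "name": "amatoxin",
    "enabled": true,
    "deltas": [
      {"name": "tryptathionine", "delta": {"H": -2}, "requires": ["W", "C"]},
      {"name": "hydroxylation_x4", "delta": {"O": 4}, "requires": []},
      {"name": "sulfoxide", "delta": {"O": 1}, "requires": ["C"]}
    ]
  },
  {
    "name": "phallotoxin",
    "enabled": false,
    "deltas": [
      {"name": "tryptathionine", "delta": {"H": -2}, "requires": ["W", "C"]},
      {"name": "hydroxylation_x3", "delta": {"O": 3}, "requires": []}
    ]
  }
]
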