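[
  {
    "zone": "anaerobic",
    "slope": 15.320,
    "intercept": 0.1033,
    "r_squared": 0.9884,
    "Ks": 148.31,
    "K": 9.68,
    "eta": 0.68
  },
  {
    "zone": "anoxic",
    "slope": 15.911,
    "intercept": 0.0880,
    "r_squared": 0.9812,
    "Ks": 180.81,
    "K": 11.36,
    "eta": 0.80
  },
  {
    "zone": "aerobic",
    "slope": 6.720,
    "intercept": 0.0701,
    "r_squared": 0.9973,
    "Ks": 95.89,
    "K": 14.27,
    "eta": 1
  }
]
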