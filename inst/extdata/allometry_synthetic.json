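[
  {
    "label": "generic eucalypt (synthetic)",
    "scope": "eucalypt",
    "alpha": -2.0,
    "beta": 2.4,
    "correction_factor": 1.0,
    "source": "synthetic coefficients for testing and examples; not an authoritative published calibration"
  },
  {
    "label": "generic rainforest (synthetic)",
    "scope": "non_eucalypt",
    "alpha": -1.8,
    "beta": 2.3,
    "correction_factor": 1.0,
    "source": "synthetic coefficients for testing and examples; not an authoritative published calibration"
  }
]
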