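[
  {
    "label": "bm_bf_cb",
    "comment": "SYNTHETIC approximate profile for biomass/biofuel/coal burning (benzene-rich, T/B < 1). Replace the vertices with measured source fingerprints before drawing conclusions.",
    "vertices": [
      [0.90, 0.09, 0.01],
      [0.50, 0.49, 0.01],
      [0.40, 0.35, 0.25],
      [0.80, 0.02, 0.18]
    ]
  },
  {
    "label": "traffic",
    "comment": "SYNTHETIC approximate profile for vehicle exhaust (T/B roughly 1-10).",
    "vertices": [
      [0.49, 0.50, 0.01],
      [0.10, 0.89, 0.01],
      [0.05, 0.65, 0.30],
      [0.38, 0.37, 0.25]
    ]
  },
  {
    "label": "industrial_solvent",
    "comment": "SYNTHETIC approximate profile for industrial process and solvent emissions (toluene/ethylbenzene-rich, T/B > 10).",
    "vertices": [
      [0.08, 0.91, 0.01],
      [0.01, 0.54, 0.45],
      [0.12, 0.43, 0.45],
      [0.06, 0.74, 0.20]
    ]
  }
]
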