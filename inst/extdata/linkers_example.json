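[
  {
    "name": "SIA",
    "spacer_angstrom": 4.2,
    "amine_side": "NHS ester",
    "thiol_side": "iodoacetamide",
    "bridge": {"C": 2, "H": 2, "O": 1}
  },
  {
    "name": "SBAP",
    "spacer_angstrom": 9.0,
    "amine_side": "NHS ester",
    "thiol_side": "bromoacetamide",
    "bridge": {"C": 5, "H": 7, "N": 1, "O": 2}
  },
  {
    "name": "SIAB",
    "spacer_angstrom": 10.6,
    "amine_side": "NHS ester",
    "thiol_side": "iodoacetamide",
    "bridge": {"C": 9, "H": 7, "N": 1, "O": 2}
  }
]
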