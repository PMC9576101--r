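[
  {
    "material": "water",
    "table": "water.tsv",
    "rho_ref": 1
  },
  {
    "material": "air",
    "table": "air.tsv",
    "rho_ref": 0.0012
  },
  {
    "material": "cortical_bone",
    "table": "cortical_bone.tsv",
    "rho_ref": 1.92
  },
  {
    "material": "adipose",
    "table": "adipose.tsv",
    "rho_ref": 0.95
  },
  {
    "material": "blood",
    "table": "blood.tsv",
    "rho_ref": 1.06
  },
  {
    "material": "skeletal_muscle",
    "table": "skeletal_muscle.tsv",
    "rho_ref": 1.05
  }
]
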