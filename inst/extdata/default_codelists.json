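{
  "cardiac": {
    "icd10": ["I50", "I42"],
    "icd9": ["428", "425"]
  },
  "liver": {
    "icd10": ["K70", "K71", "K72", "K73", "K74"],
    "icd9": "571"
  },
  "renal": {
    "icd10": ["N17", "N18"],
    "icd9": ["584", "585"]
  },
  "pulmonary": {
    "icd10": ["J44", "J84"],
    "icd9": ["496", "515"]
  },
  "neuropathy": {
    "icd10": ["G62", "G63"],
    "icd9": ["356", "357"]
  },
  "malignancy": {
    "icd10": ["C34", "C50", "C90"],
    "icd9": ["162", "174", "203"]
  }
}
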