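[
  {
    "index": 1,
    "label": "DMSO",
    "description": "0.033% dimethyl sulfoxide vehicle control (reference level)",
    "molar_concentration_uM": null,
    "molar_mass_g_mol": null,
    "mass_concentration_ug_ml": null
  },
  {
    "index": 2,
    "label": "TOFA",
    "description": "50 uM tofacitinib citrate during differentiation",
    "molar_concentration_uM": 50,
    "molar_mass_g_mol": 504.5,
    "mass_concentration_ug_ml": 25.2
  },
  {
    "index": 3,
    "label": "BUD",
    "description": "10 uM budesonide during differentiation",
    "molar_concentration_uM": 10,
    "molar_mass_g_mol": 430.5,
    "mass_concentration_ug_ml": 4.3
  },
  {
    "index": 4,
    "label": "TNF_PIC",
    "description": "TNF 100 ng/mL + Poly(I:C) 20 ug/mL stimulation on day 14",
    "molar_concentration_uM": null,
    "molar_mass_g_mol": null,
    "mass_concentration_ug_ml": null
  },
  {
    "index": 5,
    "label": "TOFA_TNF_PIC",
    "description": "tofacitinib pre-treatment followed by TNF + Poly(I:C)",
    "molar_concentration_uM": 50,
    "molar_mass_g_mol": 504.5,
    "mass_concentration_ug_ml": 25.2
  },
  {
    "index": 6,
    "label": "BUD_TNF_PIC",
    "description": "budesonide pre-treatment followed by TNF + Poly(I:C)",
    "molar_concentration_uM": 10,
    "molar_mass_g_mol": 430.5,
    "mass_concentration_ug_ml": 4.3
  }
]
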