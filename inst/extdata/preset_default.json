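{
  "name": "default",
  "version": 1,
  "description": "Synthetic-experiment preset emulating the study's qualitative pattern: competitors dominate at 1 m by the final week, panels at 3 m keep relatively more polyps and bare space, overall polyp cover low. Removal fractions at the experimental target 0.5. Dynamic parameters are in relative-abundance coordinates (delta = 1, so b0 is the product delta*b0 and a1y1 is a_{1,y1}/delta); rates are per week.",
  "dynamics": {
    "variant": "overgrowth",
    "depth_1m": {
      "a0": 0.10, "a1": 1.10, "a2": -0.12,
      "delta": 1.0, "b0": 0.004, "b1": 0.35, "b2": -0.30,
      "extra": 0.15
    },
    "depth_3m": {
      "a0": 0.035, "a1": 0.45, "a2": -0.25,
      "delta": 1.0, "b0": 0.015, "b1": 0.80, "b2": -0.20,
      "extra": 1.20
    },
    "r_A": 0.5,
    "r_O": 0.5,
    "aurita_on_competitor_share": 0.002,
    "competitor_split_alpha": {
      "botrylloides": 5, "bugula": 5, "molgula": 6,
      "ascidiella": 0.4, "botryllus": 0.4, "other": 0.7
    }
  },
  "manova": {
    "baseline_composition": [0.05, 0.30, 0.22, 0.23, 0.20],
    "depth_1m_perturbation": [0.75, 0.75, 1.30, 1.30, 1.30],
    "treatment_perturbations": {
      "A": [1.00, 1.30, 0.85, 0.85, 0.85],
      "O": [2.20, 1.30, 0.55, 0.55, 0.55]
    },
    "block_sd": 0.15,
    "panel_sd": 0.25
  }
}
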