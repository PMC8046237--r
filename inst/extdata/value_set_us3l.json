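{
  "name": "US EQ-5D-3L societal tariff (D1 model, transcribed at published rounded precision)",
  "comment": "Utility = 1 + level decrements + extra terms. Extra terms: d1 = deviations from full health beyond the first, i3 = level-3 dimensions beyond the first, i2sq/i3sq = squares of the beyond-the-first level-2/level-3 counts. Positive extra-term coefficients offset the additive main-effect decrements for multiply-impaired states.",
  "decrements": {
    "mobility":            {"2": -0.146, "3": -0.558},
    "self_care":           {"2": -0.175, "3": -0.471},
    "usual_activities":    {"2": -0.140, "3": -0.374},
    "pain_discomfort":     {"2": -0.173, "3": -0.537},
    "anxiety_depression":  {"2": -0.156, "3": -0.450}
  },
  "extra_terms": {
    "d1": 0.140,
    "i2sq": -0.011,
    "i3": 0.122,
    "i3sq": 0.015
  }
}
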