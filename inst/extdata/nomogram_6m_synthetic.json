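{
  "name": "synthetic-6-month-mortality-nomogram",
  "source": "Synthetic GRACE-style point table constructed for demonstration; not a transcription of a published nomogram. Replace with your own transcription for substantive use.",
  "variables": {
    "age": {
      "type": "continuous",
      "breakpoints": [30, 40, 50, 60, 70, 80, 90],
      "points": [0, 18, 36, 55, 73, 91, 100]
    },
    "heart_rate": {
      "type": "continuous",
      "breakpoints": [50, 70, 90, 110, 150, 200],
      "points": [0, 7, 13, 23, 36, 46]
    },
    "systolic_bp": {
      "type": "continuous",
      "breakpoints": [40, 80, 100, 120, 140, 160, 200],
      "points": [63, 58, 47, 37, 26, 11, 0]
    },
    "creatinine": {
      "type": "continuous",
      "breakpoints": [10, 35, 71, 106, 141, 177, 354],
      "points": [2, 5, 8, 11, 14, 23, 31]
    },
    "diuretic_in_hospital": { "type": "binary", "points": [24] },
    "cardiac_arrest": { "type": "binary", "points": [30] },
    "st_deviation": { "type": "binary", "points": [11] },
    "elevated_markers": { "type": "binary", "points": [15] }
  },
  "score_to_risk": {
    "score": [40, 70, 100, 120, 140, 160, 180, 200, 220, 240, 260, 280, 300, 320],
    "risk": [0.002, 0.005, 0.02, 0.04, 0.08, 0.14, 0.22, 0.34, 0.48, 0.62, 0.74, 0.84, 0.91, 0.95]
  }
}
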