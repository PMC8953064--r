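{
  "version": "1.0",
  "description": "Published raw-score performance bands for the adolescent health literacy assessments (functional, interactive, critical, and their 23-item composite; plus the ages-12-15 composite variant).",
  "presets": {
    "fhl": {
      "max_score": 6,
      "levels": {
        "label": ["Emerging", "Expanding"],
        "min_score": [0, 5],
        "max_score": [4, 6]
      }
    },
    "ihl": {
      "max_score": 10,
      "levels": {
        "label": ["Emerging", "Expanding"],
        "min_score": [0, 6],
        "max_score": [5, 10]
      }
    },
    "chl": {
      "max_score": 14,
      "levels": {
        "label": ["Emerging", "Expanding"],
        "min_score": [0, 9],
        "max_score": [8, 14]
      }
    },
    "composite": {
      "max_score": 30,
      "levels": {
        "label": ["Emerging", "Expanding", "Lower Bridging", "Upper Bridging"],
        "min_score": [0, 11, 20, 28],
        "max_score": [10, 19, 27, 30]
      }
    },
    "composite_younger": {
      "max_score": 30,
      "levels": {
        "label": ["Emerging", "Expanding", "Lower Bridging", "Upper Bridging"],
        "min_score": [0, 11, 20, 27],
        "max_score": [10, 19, 26, 30]
      }
    }
  }
}
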