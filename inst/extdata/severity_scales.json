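{
  "version": "1.0",
  "convention": "left-closed",
  "scales": {
    "daily": {
      "basis": "daily-24h",
      "unit": "kcal/24 h",
      "below_scale_label": "Light",
      "bands": [
        {"label": "Light",          "lower": 2300, "upper": 2800},
        {"label": "Moderate",       "lower": 2800, "upper": 3300},
        {"label": "Moderate hard",  "lower": 3300, "upper": 3800},
        {"label": "Hard",           "lower": 3800, "upper": 4300},
        {"label": "Very hard",      "lower": 4300, "upper": 4800},
        {"label": "Extremely hard", "lower": 4800, "upper": null}
      ]
    },
    "shift": {
      "basis": "shift-8h",
      "unit": "kcal/8 h",
      "below_scale_label": "Light",
      "bands": [
        {"label": "Light",          "lower": 0,    "upper": 500},
        {"label": "Moderate",       "lower": 500,  "upper": 1000},
        {"label": "Moderate hard",  "lower": 1000, "upper": 1500},
        {"label": "Hard",           "lower": 1500, "upper": 2000},
        {"label": "Very hard",      "lower": 2000, "upper": 2800},
        {"label": "Extremely hard", "lower": 2800, "upper": null}
      ]
    },
    "rate": {
      "basis": "per-minute",
      "unit": "kcal/min",
      "below_scale_label": "Light",
      "bands": [
        {"label": "Light",          "lower": 2.5,  "upper": 5.0},
        {"label": "Moderate",       "lower": 5.0,  "upper": 7.5},
        {"label": "Hard",           "lower": 7.5,  "upper": 10.0},
        {"label": "Very hard",      "lower": 10.0, "upper": 12.5},
        {"label": "Extremely hard", "lower": 12.5, "upper": null}
      ]
    }
  }
}
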