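{
  "air_distributions": {
    "benzene":      {"family": "lognormal10", "a": 0.321,  "b": 0.426, "unit": "ug/m3", "provenance": "configured"},
    "toluene":      {"family": "lognormal10", "a": 0.188,  "b": 0.586, "unit": "ug/m3", "provenance": "configured"},
    "ethylbenzene": {"family": "lognormal10", "a": -0.655, "b": 0.428, "unit": "ug/m3", "provenance": "configured"},
    "xylenes":      {"family": "lognormal10", "a": -0.238, "b": 0.506, "unit": "ug/m3", "provenance": "configured"}
  },
  "biomarker_distributions": {
    "ttma": {"family": "lognormal10", "a": 2.102, "b": 0.392, "unit": "ug/g crt", "provenance": "configured"},
    "spma": {"family": "lognormal10", "a": 0.441, "b": 0.298, "unit": "ug/g crt", "provenance": "configured"}
  },
  "exposure_factors": {
    "bw_male":   {"family": "normal", "a": 61.04, "b": 12.26, "unit": "kg",     "provenance": "configured"},
    "bw_female": {"family": "normal", "a": 53.72, "b": 11.08, "unit": "kg",     "provenance": "configured"},
    "ir_male":   {"family": "normal", "a": 17.02, "b": 2.96,  "unit": "m3/day", "provenance": "configured"},
    "ir_female": {"family": "normal", "a": 14.02, "b": 1.57,  "unit": "m3/day", "provenance": "configured"}
  },
  "creatinine": {"family": "lognormal10", "a": 0.0, "b": 0.17, "unit": "g/L", "provenance": "configured"},
  "thresholds": {
    "rfc": {"benzene": 30, "toluene": 5000, "ethylbenzene": 1000, "xylenes": 100},
    "bei": {"ttma": 500, "spma": 25},
    "sf": 0.029
  },
  "scenario": {"ef": 365, "ed": 53, "at": 25550},
  "monte_carlo": {"n_iterations": 10000, "risk_lines": {"acceptable": 1e-06, "serious": 1e-04}, "truncate_positive": true},
  "concentration_source": "configured",
  "sites": {
    "benzene_geomean": {"R1": 5.14, "R2": 4.41, "R3": 2.83, "R4": 0.91},
    "n_air_samples": 5
  },
  "cohorts": {
    "R1": {
      "n": 50, "n_male": 25, "smoker_rate_male": 0.680,
      "age_weights": {"20-30": 13, "31-40": 17, "41-50": 8, "51-60": 9, "61-70": 3},
      "biomarkers": {
        "ttma": {"gm": 213,  "sd": 434},
        "db12": {"gm": 91.4, "sd": 73.4},
        "spma": {"gm": 4.23, "sd": 7.68},
        "sbma": {"gm": 7.98, "sd": 7.88}
      }
    },
    "R2": {
      "n": 49, "n_male": 25, "smoker_rate_male": 0.720,
      "age_weights": {"20-30": 11, "31-40": 13, "41-50": 14, "51-60": 9, "61-70": 2},
      "biomarkers": {
        "ttma": {"gm": 128,  "sd": 197},
        "db12": {"gm": 58,   "sd": 121},
        "spma": {"gm": 2.35, "sd": 1.29},
        "sbma": {"gm": 4.7,  "sd": 10.9}
      }
    },
    "R3": {
      "n": 50, "n_male": 24, "smoker_rate_male": 0.625,
      "age_weights": {"20-30": 15, "31-40": 10, "41-50": 13, "51-60": 7, "61-70": 4},
      "biomarkers": {
        "ttma": {"gm": 83,   "sd": 164},
        "db12": {"gm": 62.8, "sd": 65.9},
        "spma": {"gm": 2.30, "sd": 1.49},
        "sbma": {"gm": 6.90, "sd": 4.80}
      }
    },
    "R4": {
      "n": 25, "n_male": 11, "smoker_rate_male": 0.818,
      "age_weights": {"20-30": 4, "31-40": 7, "41-50": 4, "51-60": 8, "61-70": 2},
      "biomarkers": {
        "ttma": {"gm": 98.1, "sd": 75.8},
        "db12": {"gm": 43,   "sd": 120},
        "spma": {"gm": 2.06, "sd": 0.76},
        "sbma": {"gm": 7.6,  "sd": 13.9}
      }
    }
  }
}
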