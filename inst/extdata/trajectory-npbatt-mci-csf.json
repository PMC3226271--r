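{
  "type": "trajectory",
  "terms": ["(Intercept)", "visit", "csf_ratio", "faq_bl", "adascog_bl", "npbatt_bl", "csf_ratio:visit", "adascog_bl:visit"],
  "coefficients": {
    "(Intercept)": 0.19832,
    "visit": -0.07163,
    "csf_ratio": 0.00328,
    "faq_bl": -0.01015,
    "adascog_bl": 0.00058,
    "npbatt_bl": 0.99973,
    "csf_ratio:visit": 0.02229,
    "adascog_bl:visit": -0.00398
  },
  "vcov": [
    [
      0.0087890625,
      0,
      0,
      0,
      0,
      0,
      0,
      0
    ],
    [
      0,
      0.0011195716,
      0,
      0,
      0,
      0,
      0,
      0
    ],
    [
      0,
      0,
      0.0002356225,
      0,
      0,
      0,
      0,
      0
    ],
    [
      0,
      0,
      0,
      2.58064e-05,
      0,
      0,
      0,
      0
    ],
    [
      0,
      0,
      0,
      0,
      2.14369e-05,
      0,
      0,
      0
    ],
    [
      0,
      0,
      0,
      0,
      0,
      0.0019123129,
      0,
      0
    ],
    [
      0,
      0,
      0,
      0,
      0,
      0,
      3.00304e-05,
      0
    ],
    [
      0,
      0,
      0,
      0,
      0,
      0,
      0,
      2.1316e-06
    ]
  ],
  "ranef": {
    "sd_intercept": 0.1816,
    "sd_slope": 0.0698,
    "cor": 0.5598
  },
  "within_sd": 0.2512,
  "time_unit": "visit",
  "n_subjects": 189,
  "coding": {
    "gender_reference": "male",
    "bmi_cutoffs": [25, 30],
    "obesity_definition": "bmi3"
  },
  "provenance": {
    "created": "2026-09-21T00:00:00+0000",
    "package": "pgsa 0.1.0",
    "note": "Published coefficient table from an ADNI MCI cohort analysis; covariance matrix is a synthetic diagonal approximation built from the printed standard errors (off-diagonals unpublished).",
    "n": 189,
    "seed": null
  }
}
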