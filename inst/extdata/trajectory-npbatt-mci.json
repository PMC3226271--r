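{
  "type": "trajectory",
  "terms": ["(Intercept)", "bmi2", "bmi3", "visit", "apoe4", "age", "faq_bl", "adascog_bl", "npbatt_bl", "bmi2:visit", "bmi3:visit", "apoe4:visit", "adascog_bl:visit", "age:faq_bl"],
  "coefficients": {
    "(Intercept)": 0.92879,
    "bmi2": -0.06911,
    "bmi3": -0.04498,
    "visit": 0.01241,
    "apoe4": 0.03383,
    "age": -0.00887,
    "faq_bl": -0.11273,
    "adascog_bl": -0.00299,
    "npbatt_bl": 0.97529,
    "bmi2:visit": 0.0213,
    "bmi3:visit": 0.05513,
    "apoe4:visit": -0.03558,
    "adascog_bl:visit": -0.00557,
    "age:faq_bl": 0.0014
  },
  "vcov": [
    [
      0.0514518489,
      0,
      0,
      0,
      0,
      0,
      0,
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
      0.0014531344,
      0,
      0,
      0,
      0,
      0,
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
      0,
      0.0028483569,
      0,
      0,
      0,
      0,
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
      0,
      0,
      0.0004769856,
      0,
      0,
      0,
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
      0,
      0,
      0,
      0.0006801664,
      0,
      0,
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
      0,
      0,
      0,
      0,
      8.5264e-06,
      0,
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
      0,
      0,
      0,
      0,
      0,
      0.0014707225,
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
      0,
      0,
      0,
      0,
      0,
      0,
      1.14921e-05,
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
      0,
      0,
      0,
      0,
      0,
      0,
      0.0009114361,
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
      0,
      0,
      0,
      0,
      0,
      0,
      0.0001865956,
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
      0,
      0,
      0,
      0,
      0,
      0,
      0.0004012009,
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
      0,
      0,
      0,
      0,
      0,
      0,
      8.68624e-05,
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
      0,
      0,
      0,
      0,
      0,
      0,
      1.0816e-06,
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
      0,
      0,
      0,
      0,
      0,
      0,
      2.601e-07
    ]
  ],
  "ranef": {
    "sd_intercept": 0.1856,
    "sd_slope": 0.0677,
    "cor": 0.6544
  },
  "within_sd": 0.25,
  "time_unit": "visit",
  "n_subjects": 375,
  "coding": {
    "gender_reference": "male",
    "bmi_cutoffs": [25, 30],
    "obesity_definition": "bmi3"
  },
  "provenance": {
    "created": "2026-09-21T00:00:00+0000",
    "package": "pgsa 0.1.0",
    "note": "Published coefficient table from an ADNI MCI cohort analysis; covariance matrix is a synthetic diagonal approximation built from the printed standard errors (off-diagonals unpublished).",
    "n": 375,
    "seed": null
  }
}
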