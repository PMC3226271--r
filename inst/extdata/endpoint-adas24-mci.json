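{
  "type": "endpoint",
  "terms": ["(Intercept)", "gender", "obesity", "faq_bl", "mmse_bl", "adascog_bl", "npbatt_bl", "faq_bl:npbatt_bl"],
  "coefficients": {
    "(Intercept)": 3.84232,
    "gender": 0.28474,
    "obesity": -0.27526,
    "faq_bl": 0.07902,
    "mmse_bl": -0.06994,
    "adascog_bl": 0.0925,
    "npbatt_bl": -0.50529,
    "faq_bl:npbatt_bl": 0.03762
  },
  "vcov": [
    [
      0.5848119729,
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
      0.0070341769,
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
      0.01364224,
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
      0.0003193369,
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
      0.0006421156,
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
      5.89824e-05,
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
      0.00777924,
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
      0.0001798281
    ]
  ],
  "residual_sd": 0.669,
  "transform": "sqrt",
  "n": 286,
  "coding": {
    "gender_reference": "male",
    "bmi_cutoffs": [25, 30],
    "obesity_definition": "bmi3"
  },
  "provenance": {
    "created": "2026-09-21T00:00:00+0000",
    "package": "pgsa 0.1.0",
    "note": "Published coefficient table from an ADNI MCI cohort analysis; covariance matrix is a synthetic diagonal approximation built from the printed standard errors (off-diagonals unpublished).",
    "n": 286,
    "seed": null
  }
}
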