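{
  "version": "illustrative-0.1 (synthetic, non-canonical)",
  "equations": [
    {
      "name": "mi",
      "kind": "event",
      "baseline_form": "exponential",
      "intercept": -4.017,
      "coefficients": {"hba1c": 0.12, "sbp": 0.008, "ldl": 0.22, "hdl": -0.4,
                       "smoker": 0.35, "male": 0.25, "age": 0.05,
                       "prior_mi": 0.6, "event_mi": 0.4},
      "centers": {"hba1c": 7.5, "sbp": 135, "ldl": 2.5, "hdl": 1.1, "age": 65},
      "case_fatality": 0.15
    },
    {
      "name": "stroke",
      "kind": "event",
      "baseline_form": "exponential",
      "intercept": -4.711,
      "coefficients": {"sbp": 0.012, "afib": 0.7, "age": 0.06,
                       "smoker": 0.3, "prior_stroke": 0.6},
      "centers": {"sbp": 135, "age": 65},
      "case_fatality": 0.12
    },
    {
      "name": "ihd",
      "kind": "event",
      "baseline_form": "exponential",
      "intercept": -3.912,
      "coefficients": {"ldl": 0.18, "hdl": -0.3, "age": 0.04, "male": 0.2},
      "centers": {"ldl": 2.5, "hdl": 1.1, "age": 65},
      "excluded_if_prior": ["prior_ihd"]
    },
    {
      "name": "hf",
      "kind": "event",
      "baseline_form": "exponential",
      "intercept": -5.116,
      "coefficients": {"sbp": 0.006, "hba1c": 0.08, "age": 0.07,
                       "afib": 0.5, "egfr": -0.01},
      "centers": {"sbp": 135, "hba1c": 7.5, "age": 65, "egfr": 75},
      "excluded_if_prior": ["prior_hf"]
    },
    {
      "name": "cv_death",
      "kind": "death",
      "baseline_form": "gompertz",
      "shape": 0.02,
      "intercept": -4.828,
      "coefficients": {"age": 0.08, "hba1c": 0.06, "egfr": -0.012,
                       "event_mi": 0.8, "event_stroke": 0.7, "event_hf": 0.6,
                       "prior_mi": 0.4},
      "centers": {"age": 65, "hba1c": 7.5, "egfr": 75},
      "fatal_class": "cv"
    },
    {
      "name": "noncv_death",
      "kind": "death",
      "baseline_form": "gompertz",
      "shape": 0.03,
      "intercept": -4.423,
      "coefficients": {"age": 0.09, "smoker": 0.4, "wbc": 0.04,
                       "haemoglobin": -0.08},
      "centers": {"age": 65, "wbc": 7.5, "haemoglobin": 13.8},
      "fatal_class": "noncv"
    },
    {"name": "hba1c", "kind": "progression", "baseline_form": "linear",
     "intercept": 0.05, "coefficients": {"current": 1}},
    {"name": "sbp", "kind": "progression", "baseline_form": "linear",
     "intercept": 2.7, "coefficients": {"current": 0.98}},
    {"name": "weight", "kind": "progression", "baseline_form": "linear",
     "intercept": 0, "coefficients": {"current": 1}},
    {"name": "hdl", "kind": "progression", "baseline_form": "linear",
     "intercept": 0, "coefficients": {"current": 1}},
    {"name": "ldl", "kind": "progression", "baseline_form": "linear",
     "intercept": 0, "coefficients": {"current": 1}},
    {"name": "heart_rate", "kind": "progression", "baseline_form": "linear",
     "intercept": 0, "coefficients": {"current": 1}},
    {"name": "wbc", "kind": "progression", "baseline_form": "linear",
     "intercept": 0, "coefficients": {"current": 1}},
    {"name": "haemoglobin", "kind": "progression", "baseline_form": "linear",
     "intercept": 0, "coefficients": {"current": 1}},
    {"name": "egfr", "kind": "progression", "baseline_form": "linear",
     "intercept": -0.8, "coefficients": {"current": 1}}
  ]
}
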