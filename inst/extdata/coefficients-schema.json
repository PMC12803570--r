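{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "t2dsim coefficient set",
  "type": "object",
  "required": ["equations"],
  "properties": {
    "version": {"type": "string"},
    "equations": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "kind", "baseline_form"],
        "properties": {
          "name": {"type": "string",
            "description": "endpoint name (event/death) or risk-factor name (progression); unique within the file"},
          "kind": {"enum": ["event", "death", "progression"]},
          "baseline_form": {"enum": ["exponential", "weibull", "gompertz", "logistic", "linear"],
            "description": "'linear' only with kind=progression; the hazard and logistic forms only with kind=event/death"},
          "intercept": {"type": "number"},
          "coefficients": {
            "type": "object",
            "additionalProperties": {"type": "number"},
            "description": "covariate name -> per-unit weight; names must resolve to a registry covariate ('current' additionally allowed in progression equations)"
          },
          "centers": {
            "type": "object",
            "additionalProperties": {"type": "number"},
            "description": "optional centering constants; contribution is coef * (x - center)"
          },
          "shape": {"type": "number", "exclusiveMinimum": 0,
            "description": "required for weibull/gompertz baselines"},
          "time_scale": {"enum": ["simulation", "duration"],
            "description": "time axis for weibull/gompertz; default 'simulation'"},
          "excluded_if_prior": {"type": "array", "items": {"type": "string"},
            "description": "prior-event flags that exclude a participant from ever experiencing this (first-event-only) endpoint"},
          "case_fatality": {"type": "number", "minimum": 0, "maximum": 1,
            "description": "event equations: probability a fired event is fatal (counts as a cardiovascular death)"},
          "fatal_class": {"enum": ["cv", "noncv"],
            "description": "death equations: cardiovascular or non-cardiovascular"},
          "ua_fraction": {"type": "number", "minimum": 0, "maximum": 1,
            "description": "probability a fired event also registers an unstable-angina proxy event; default 0"}
        }
      }
    }
  }
}
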