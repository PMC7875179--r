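{
  "betas": {
    "age": 0.01,
    "male": 0.457,
    "age_male": -0.009,
    "White": 0,
    "Black": 0.995,
    "Asian": 0.487,
    "Mixed": 0.686,
    "Other": 0.34,
    "ARMS": 0,
    "Acute-transient-psychotic": 1.169,
    "Substance-use": -1.748,
    "Bipolar-mood": 0.003,
    "Non-bipolar-mood": -1.56,
    "Anxiety": -2.006,
    "Personality": -1.363,
    "Developmental": -3.337,
    "Childhood-adolescence-onset": -3.2,
    "Physiological-syndromes": -2.31,
    "Mental-retardation": -2.326
  },
  "baseline": {
    "form": "exponential",
    "rate": 0.000238060784247727
  },
  "horizon_days": 730
}
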