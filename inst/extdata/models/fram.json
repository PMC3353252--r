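{
  "name": "FRAM",
  "provenance": "published",
  "intercept": null,
  "terms": [
    {"name": "ifg", "field": "fpg", "encoding": "range", "lower": 6.1, "upper": 7.0, "beta": 1.98},
    {"name": "elevated_sbp", "field": "sbp", "encoding": "threshold", "cutpoint": 130, "direction": "ge", "beta": 0.50},
    {"name": "elevated_triglyceride", "field": "triglyceride", "encoding": "threshold", "cutpoint": 1.7, "direction": "ge", "beta": 0.58},
    {"name": "low_hdl", "field": "hdl", "encoding": "threshold", "cutpoint": 1.0, "cutpoint_female": 1.3, "direction": "lt", "beta": 0.94},
    {"name": "overweight", "field": "bmi", "encoding": "range", "lower": 25, "upper": 30, "beta": 0.30},
    {"name": "obese", "field": "bmi", "encoding": "threshold", "cutpoint": 30, "direction": "ge", "beta": 0.92},
    {"name": "family_history", "field": "family_history_t2dm", "encoding": "binary", "beta": 0.57}
  ]
}
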