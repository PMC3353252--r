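{
  "name": "SAHS",
  "provenance": "published",
  "intercept": null,
  "terms": [
    {"name": "age", "field": "age", "encoding": "linear", "beta": 0.028},
    {"name": "gender", "field": "sex", "encoding": "female", "beta": 0.661},
    {"name": "ethnicity", "field": "ethnicity", "encoding": "non_chinese", "beta": 0.412},
    {"name": "fpg", "field": "fpg", "encoding": "linear", "unit": "mg/dl", "beta": 0.079},
    {"name": "sbp", "field": "sbp", "encoding": "linear", "beta": 0.018},
    {"name": "hdl", "field": "hdl", "encoding": "linear", "unit": "mg/dl", "beta": -0.039},
    {"name": "bmi", "field": "bmi", "encoding": "linear", "beta": 0.070},
    {"name": "family_history", "field": "family_history_t2dm", "encoding": "binary", "beta": 0.481}
  ]
}
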