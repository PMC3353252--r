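{
  "name": "ARIC",
  "provenance": "published",
  "intercept": null,
  "terms": [
    {"name": "age", "field": "age", "encoding": "linear", "beta": 0.0173},
    {"name": "ethnicity", "field": "ethnicity", "encoding": "non_chinese", "beta": 0.4433},
    {"name": "fpg", "field": "fpg", "encoding": "linear", "unit": "mg/dl", "beta": 0.0880},
    {"name": "sbp", "field": "sbp", "encoding": "linear", "beta": 0.0111},
    {"name": "triglyceride", "field": "triglyceride", "encoding": "linear", "unit": "mg/dl", "beta": 0.0027},
    {"name": "hdl", "field": "hdl", "encoding": "linear", "unit": "mg/dl", "beta": -0.0122},
    {"name": "waist", "field": "waist", "encoding": "linear", "beta": 0.0273},
    {"name": "height", "field": "height", "encoding": "linear", "beta": -0.0326},
    {"name": "family_history", "field": "family_history_t2dm", "encoding": "binary", "beta": 0.4981}
  ]
}
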