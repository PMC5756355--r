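{
  "name": "china_crc_2012",
  "z": 1.96,
  "use_printed_rrs": true,
  "pooling": {"urban_weight": 0.3333333333333333},
  "factors": {
    "name": ["tobacco_smoking", "alcohol_drinking", "overweight_obesity",
             "physical_inactivity", "low_vegetable_intake", "low_fruit_intake",
             "high_red_processed_meat_intake"],
    "kind": ["binary", "binary", "multi_level", "binary",
             "quantile_dose_response", "quantile_dose_response",
             "quantile_dose_response"],
    "direction": ["harmful", "harmful", "harmful", "harmful",
                  "protective", "protective", "harmful"]
  },
  "tables": {
    "exposure": "exposure.csv",
    "burden": "burden.csv",
    "published_pafs": "published_pafs.csv"
  }
}
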