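version: 1
lh_surge:
  threshold_ng_ml: 3.8
  sd_multiplier: 3
  strict: true
assay_ranges:
  LH:
    lower_ng_ml: 0.16
    upper_ng_ml: 40
  corticosterone:
    lower_ng_ml: 3.9
    upper_ng_ml: 1000
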