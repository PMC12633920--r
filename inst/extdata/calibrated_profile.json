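{
  "rep_cost": 0.334229258175035,
  "rep_mid_threshold": 0.705758743681877,
  "rep_curve_shape": 48.7690889493744,
  "wb_age_threshold": 31.5495938940679,
  "wb_intercept_C": 0.0142894356312015,
  "wb_exp_gain": 1.08939459580257,
  "wb_exp_loss": 0.847171214806598,
  "wb_max_inc": 0.0189358847030649,
  "marriage_age_diff": 3.05710090719124,
  "metadata": {
    "procedure": "best of 10 optimisation experiments (seeds 43-52)",
    "winning_seed": 48,
    "budget": 700,
    "replicates": 6,
    "horizon": 500,
    "score": 0.0102037210897938,
    "produced_by": "prosoceq::calibrate_reference_model"
  }
}
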