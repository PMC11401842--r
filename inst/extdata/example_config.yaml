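# Example run configuration: every key is optional; omitted sections use
# package defaults. Units: ages in years, rates per year, costs in GBP.
cohort:
  n: 50000
  seed: 1
  sex_split: 0.5
  smoking_probs: [0.55, 0.35, 0.10]

natural_history:
  incidental_detection_rate: 0.05
  surveillance_dropout_rate: 0.02
  diagnosis_threshold: 3.0

policy:
  sex: male
  invite_age: 62
  attendance_prob: 0.75
  referral_threshold: 5.5

econ:
  wtp: 30000
  discount_rate: 0.035
  genotyping_cost: 0

seeds:
  cohort: 1
  des: 2
  psa: 3
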