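{
  "n_per_group": {
    "regulator_100k": 97,
    "seller_100k": 101,
    "regulator_1": 105,
    "seller_1": 101
  },
  "base_price_mean": {
    "regulator_100k": 1.5,
    "seller_100k": 1.7,
    "regulator_1": 1.9,
    "seller_1": 1.6
  },
  "base_price_sd": 0.6,
  "increment_mean": 0.15,
  "zero_margin_prob": 0.09,
  "persistent_zero_prob": 0.15,
  "positive_margin_mean": 0.2,
  "inconsistency_prob": 0.1,
  "non_monotone_prob": 0.25,
  "screening_correct_prob": 0.88,
  "comprehension_correct_prob": 0.85
}
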