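{
  "price_min": 50,
  "price_max": 500,
  "monthly_salary_healthy": 10,
  "decider_fixed_salary": 120,
  "payer_premium_per_payer": 120,
  "n_payers": 2,
  "n_investors": 2,
  "initial_asset_per_funder": 120,
  "conversion_factor": 100000,
  "payoff_divisor": 10,
  "rounds": [
    {
      "index": -1,
      "state": "no_product",
      "survival_m": 0,
      "quality_q": 0.5
    },
    {
      "index": 0,
      "state": "soc",
      "survival_m": 5,
      "quality_q": 0.5
    },
    {
      "index": 1,
      "state": "product_1",
      "survival_m": 8,
      "quality_q": 0.5
    },
    {
      "index": 2,
      "state": "product_2",
      "survival_m": 10,
      "quality_q": 0.5
    },
    {
      "index": 3,
      "state": "product_3",
      "survival_m": 12,
      "quality_q": 0.5
    },
    {
      "index": 4,
      "state": "product_4",
      "survival_m": 15,
      "quality_q": 0.5
    },
    {
      "index": 5,
      "state": "product_5",
      "survival_m": 17,
      "quality_q": 0.5
    }
  ]
}
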