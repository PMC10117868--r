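criterion,distance
meat_total,0.897
crop_per_million,1.769
producer_support_pct,0.373
producer_protection_ratio,0.018
household_spending_pct_gdp,0.790
food_inflation_pct,0.078
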