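label,Dimension_1,Dimension_2
meat_total,-0.011,0.535
crop_per_million,1.351,-0.220
producer_support_pct,-0.185,0.027
producer_protection_ratio,-0.408,-0.250
household_spending_pct_gdp,0.056,0.367
food_inflation_pct,-0.386,-0.194
Factor_1,-0.417,-0.266
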