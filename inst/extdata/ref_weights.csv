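criterion,distance,ratio,fixed,weight
meat_total,0.897,0.228552737,0.771447263,0.154289453
crop_per_million,1.769,0.450521561,0.549478439,0.109895688
producer_support_pct,0.373,0.095106865,0.904893135,0.180978627
producer_protection_ratio,0.018,0.004690236,0.995309764,0.199061953
household_spending_pct_gdp,0.790,0.201268933,0.798731067,0.159746213
food_inflation_pct,0.078,0.019859668,0.980140332,0.196028066
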