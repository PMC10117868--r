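country,meat_beef,meat_pork,meat_poultry,meat_sheep,meat_total,crop_wheat,crop_maize,crop_rice,crop_soybean,crop_total,population,crop_per_million,producer_support_pct,producer_protection_ratio,household_spending_pct_gdp,food_inflation_pct,gdp_growth_pct,health_spending,gdp_per_capita,population_as_printed
Australia,19.44,20.21,43.79,5.87,89.32,31164.50,200.79,380.00,44.06,31789.35,25693267,1237.25,3.29,1.00,50.66,9.32,-2.21,5627.32,55996.38,FALSE
Canada,17.58,15.88,35.53,0.97,69.96,35188.18,13563.41,0.00,6358.55,55110.14,38037204,1448.85,8.18,1.05,57.16,2.40,-5.23,5828.32,46572.14,FALSE
Chile,20.26,24.76,37.07,0.48,82.58,1300.00,594.48,117.57,0.00,2012.05,1945831,1034.03,2.43,1.00,57.77,6.74,-6.21,2412.75,24647.94,TRUE
Colombia,8.62,8.99,31.70,0.14,49.46,5.00,1430.00,2005.82,75.00,3515.82,50911747,69.06,10.16,1.10,70.51,5.55,-7.05,1335.88,15306.34,FALSE
Israel,23.21,1.31,64.44,1.53,90.49,85.00,81.00,0.00,0.00,166.00,9215113,18.01,15.36,1.16,48.42,0.0,-1.78,3057.41,40090.87,FALSE
Japan,7.64,16.13,17.73,0.16,41.67,1037.00,0.00,7396.39,241.65,8675.04,126146099,68.77,43.50,1.66,53.79,1.20,-4.62,4665.64,42285.33,FALSE
Korea,11.85,31.57,18.74,0.33,62.49,27.15,73.58,3996.48,98.98,4196.20,51836239,80.95,47.91,1.73,46.39,4.43,-0.71,3582.31,45403.24,FALSE
Mexico,8.97,14.42,30.59,0.54,54.52,2957.48,275599.39,358.23,268.41,279183.51,127792286,2184.66,9.52,1.06,63.07,6.62,-8.06,1226.74,19106.97,FALSE
New Zealand,11.55,19.06,40.08,3.45,74.14,482.06,181.77,0.00,0.00,663.83,50902,13041.39,0.98,1.01,57.50,3.18,-1.06,4469.38,44698.27,TRUE
Norway,12.81,21.10,17.84,4.48,56.22,468.97,0.00,0.00,0.00,468.97,5379472,87.18,53.40,1.61,43.98,3.26,-0.72,6536.09,62650.38,FALSE
Switzerland,13.11,22.46,14.77,1.15,51.48,445.99,146.69,0.27,5.93,598.88,863817,693.28,52.65,1.60,51.61,0.09,-2.51,7178.56,70555.78,TRUE
Turkey,9.63,0.00,19.18,4.23,33.05,20500.00,6031.00,588.00,140.00,27259.00,83384688,326.91,26.03,1.16,56.77,13.85,1.83,1304.71,27554.34,FALSE
United Kingdom,11.33,15.82,30.45,3.93,61.52,10132.99,0.00,0.00,0.00,10132.99,67081234,151.06,18.92,1.05,59.86,0.70,-11.03,5018.70,45644.39,FALSE
United States,26.20,23.98,50.96,0.43,101.57,49696.42,360251.16,6738.04,112538.16,529223.78,33150108,15964.47,11.62,1.02,67.03,3.51,-2.77,11859.18,63480.86,TRUE
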