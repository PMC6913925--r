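# Calibration of the synthetic-study generator: mean (mu) and SD (sigma) of
# log10 E. coli concentration per sample type, in matrix reporting units
# (waters MPN/100 mL, latrine swabs MPN/swab, produce MPN/serving, street
# food and soil MPN/gram). stratum_type "overall" pools all neighborhoods
# (its sigma mixes between- and within-neighborhood variance); "category"
# rows are per neighborhood category; "corporation" rows are the municipal
# drinking-water means per city corporation (no SD published).
sample_type,stratum_type,stratum,mu,sigma,n
latrine_swab,overall,overall,0.20,0.73,100
soil,overall,overall,2.29,1.29,100
drain_water,overall,overall,6.91,0.92,100
bathing_water,overall,overall,1.34,1.34,100
municipal_water,overall,overall,1.17,1.55,100
non_municipal_water,overall,overall,0.45,0.94,100
surface_water,overall,overall,5.28,1.37,100
produce,overall,overall,3.19,1.36,100
street_food,overall,overall,1.79,1.18,100
floodwater,overall,overall,4.60,1.02,100
latrine_swab,category,low_income,0.22,0.72,40
latrine_swab,category,high_income,0.07,0.63,40
latrine_swab,category,floating,0.42,0.91,20
soil,category,low_income,2.55,1.34,40
soil,category,high_income,1.63,1.16,40
soil,category,floating,3.09,0.79,20
drain_water,category,low_income,7.11,0.86,40
drain_water,category,high_income,6.95,0.84,40
drain_water,category,floating,6.46,1.11,20
bathing_water,category,low_income,1.92,1.32,40
bathing_water,category,high_income,0.94,1.23,40
bathing_water,category,floating,0.99,1.24,20
municipal_water,category,low_income,1.55,1.73,40
municipal_water,category,high_income,1.07,1.41,40
municipal_water,category,floating,0.64,1.30,20
non_municipal_water,category,low_income,0.81,1.19,40
non_municipal_water,category,high_income,0.18,0.60,40
non_municipal_water,category,floating,0.26,0.73,20
surface_water,category,low_income,6.21,1.01,40
surface_water,category,high_income,4.29,1.01,40
surface_water,category,floating,5.40,1.32,20
produce,category,low_income,3.10,1.13,40
produce,category,high_income,3.15,1.37,40
produce,category,floating,3.45,1.49,20
street_food,category,low_income,1.62,1.11,40
street_food,category,high_income,1.91,1.21,40
street_food,category,floating,1.92,1.28,20
floodwater,category,low_income,4.86,0.88,40
floodwater,category,high_income,4.38,0.98,40
floodwater,category,floating,4.51,1.28,20
municipal_water,corporation,DSCC,1.89,NA,50
municipal_water,corporation,DNCC,0.46,NA,50
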