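factor,degree,rank
resident_population,0.490,8
pct_aged_65_plus,0.644,4
dependency_ratio,0.635,5
urbanization_level,0.523,7
per_capita_gdp,0.667,3
per_capita_disposable_income,0.673,2
per_capita_health_expenditure,0.800,1
health_expenditure_gdp_ratio,0.569,6
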