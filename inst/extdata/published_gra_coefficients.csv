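year,resident_population,pct_aged_65_plus,dependency_ratio,urbanization_level,per_capita_gdp,per_capita_disposable_income,per_capita_health_expenditure,health_expenditure_gdp_ratio
2017,0.335,0.476,0.424,0.369,0.569,0.569,0.726,0.383
2018,0.451,0.634,0.574,0.487,0.645,0.672,0.803,0.519
2019,0.677,0.832,0.860,0.699,0.805,0.778,0.855,0.703
2020,0.708,0.833,0.998,0.750,0.674,0.781,0.932,1.000
2021,0.432,0.582,0.544,0.467,0.698,0.662,0.671,0.424
2022,0.339,0.509,0.413,0.368,0.612,0.574,0.814,0.384
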