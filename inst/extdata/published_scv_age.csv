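year,scv_under_25,scv_25_34,scv_35_44,scv_45_54,scv_55_59,scv_60_plus,scd,scc_under_25,scc_25_34,scc_35_44,scc_45_54,scc_55_59,scc_60_plus
2017,0.001,-0.014,0.007,-0.001,0.001,0.006,3.00,3.33,46.67,23.33,3.33,3.33,20.00
2018,0.001,-0.012,0.011,-0.012,0.013,-0.001,5.00,2.00,24.00,22.00,24.00,26.00,2.00
2019,0.003,0.021,-0.009,-0.012,0.000,-0.003,4.80,6.25,43.75,18.75,25.00,0.00,6.25
2020,0.018,0.050,-0.024,-0.023,-0.008,-0.013,13.60,13.24,36.76,17.65,16.91,5.88,9.56
2021,-0.001,-0.004,0.009,-0.004,0.001,-0.001,2.00,5.00,20.00,45.00,20.00,5.00,5.00
2022,0.000,-0.002,0.014,0.000,-0.005,-0.007,2.80,0.00,7.14,50.00,0.00,17.86,25.00
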