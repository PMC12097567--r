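year,scv_senior,scv_associate,scv_intermediate,scv_division_assistant,scv_bachelor,scv_unspecified,scd,scc_senior,scc_associate,scc_intermediate,scc_division_assistant,scc_bachelor,scc_unspecified
2017,-0.001,-0.002,-0.010,-0.005,-0.003,0.021,4.20,2.38,4.76,23.81,11.90,7.14,50.00
2018,0.000,-0.003,-0.005,0.024,0.012,-0.028,7.20,0.00,4.17,6.94,33.33,16.67,38.89
2019,-0.001,-0.003,-0.007,0.008,0.007,-0.004,3.00,3.33,10.00,23.33,26.67,23.33,13.33
2020,0.000,-0.001,-0.003,-0.001,0.005,0.000,1.00,0.00,10.00,30.00,10.00,50.00,0.00
2021,0.002,0.004,0.023,0.015,-0.003,-0.041,8.80,2.27,4.55,26.14,17.05,3.41,46.59
2022,-0.001,-0.001,0.010,0.011,0.001,-0.020,4.40,2.27,2.27,22.73,25.00,2.27,45.45
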