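year,scv_under_5y,scv_5_9y,scv_10_19y,scv_20_29y,scv_30y_plus,scd,scc_under_5y,scc_5_9y,scc_10_19y,scc_20_29y,scc_30y_plus
2017,0.008,0.005,-0.002,-0.006,-0.005,2.60,30.77,19.23,7.69,23.08,19.23
2018,-0.010,0.010,0.006,-0.004,-0.002,3.20,31.25,31.25,18.75,12.50,6.25
2019,0.030,-0.002,-0.005,-0.016,-0.007,6.00,50.00,3.33,8.33,26.67,11.67
2020,0.085,-0.007,-0.025,-0.025,-0.028,17.00,50.00,4.12,14.71,14.71,16.47
2021,-0.003,0.006,0.005,-0.009,0.001,2.40,12.50,25.00,20.83,37.50,4.17
2022,-0.009,0.008,0.014,-0.004,-0.009,4.40,20.45,18.18,31.82,9.09,20.45
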