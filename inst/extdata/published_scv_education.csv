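year,scv_postgraduate,scv_undergraduate,scv_college,scv_junior_college,scv_high_school_below,scd,scc_postgraduate,scc_undergraduate,scc_college,scc_junior_college,scc_high_school_below
2017,0.004,0.009,0.000,-0.011,-0.002,2.60,15.38,34.62,0.00,42.31,7.69
2018,0.001,0.010,0.013,-0.022,-0.002,4.80,2.08,20.83,27.08,45.83,4.17
2019,-0.002,0.004,0.012,-0.011,-0.003,3.20,6.25,12.50,37.50,34.38,9.38
2020,-0.002,0.020,0.006,-0.021,-0.003,5.20,3.85,38.46,11.54,40.38,5.77
2021,0.008,0.010,-0.006,-0.011,-0.001,3.60,22.22,27.78,16.67,30.56,2.78
2022,0.001,-0.002,0.009,-0.008,0.000,2.00,5.00,10.00,45.00,40.00,0.00
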