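temperature_C,concentration_pct,TPC_mean,TPC_sd,TFC_mean,TFC_sd,TC_mean,TC_sd,TAC_mean,TAC_sd
30,0,3.41,0.21,1.83,0.03,0.27,0.02,0.02,0.01
30,40,4.78,0.18,3.04,0.12,0.47,0.02,0.35,0.01
30,60,7.51,0.25,4.89,0.09,0.84,0.03,0.67,0.01
30,80,5.76,0.18,4.31,0.10,0.74,0.05,0.45,0.01
30,96,1.37,0.11,0.84,0.03,0.11,0.01,0.23,0.01
45,0,4.30,0.14,2.50,0.03,0.35,0.04,0.03,0.01
45,40,5.77,0.22,3.85,0.11,0.57,0.04,0.56,0.01
45,60,9.52,0.24,6.87,0.07,1.11,0.07,0.79,0.01
45,80,7.14,0.13,5.43,0.05,0.95,0.04,0.62,0.01
45,96,1.73,0.11,0.94,0.04,0.14,0.02,0.29,0.01
65,0,5.35,0.18,3.32,0.04,0.53,0.02,0.05,0.01
65,40,8.69,0.17,5.98,0.08,1.16,0.04,0.71,0.01
65,60,11.02,0.02,7.76,0.14,1.37,0.01,0.97,0.02
65,80,9.40,0.10,7.38,0.15,1.24,0.04,0.79,0.01
65,96,2.39,0.10,1.48,0.04,0.18,0.01,0.38,0.01
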