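treatment,year,et_mm,et_sd,yield_t_ha,yield_sd
W1N1,2022,275.88,6.80,63.57,1.49
W2N1,2022,289.92,5.60,72.12,1.80
W3N1,2022,321.02,6.35,72.74,2.52
W1N2,2022,271.40,6.45,66.15,2.48
W2N2,2022,298.07,6.06,87.87,1.97
W3N2,2022,333.13,6.94,85.60,1.67
W1N3,2022,266.73,7.07,58.81,2.25
W2N3,2022,301.60,6.41,77.23,1.44
W3N3,2022,337.19,6.08,79.32,2.87
CK,2022,314.44,6.07,65.06,1.92
W1N1,2023,268.78,4.68,62.22,0.96
W2N1,2023,282.24,4.27,70.04,2.13
W3N1,2023,314.97,10.14,70.99,0.40
W1N2,2023,264.24,6.61,67.56,1.15
W2N2,2023,291.54,6.83,86.50,1.90
W3N2,2023,334.62,8.96,84.97,1.20
W1N3,2023,254.90,9.60,61.38,1.42
W2N3,2023,287.71,8.79,78.38,1.27
W3N3,2023,330.07,7.61,80.28,0.73
CK,2023,307.99,8.75,63.18,1.98
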