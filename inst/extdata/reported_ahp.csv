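matrix,item,reported_weight,reported_lambda_max,reported_ci,reported_cr
criterion,M,0.3854,NA,NA,NA
criterion,O,0.2976,NA,NA,NA
criterion,A,0.1275,NA,NA,NA
M,M1,0.1560,8.552,0.079,0.056
M,M2,0.1428,8.552,0.079,0.056
M,M3,0.1426,8.552,0.079,0.056
M,M4,0.0964,8.552,0.079,0.056
M,M5,0.0948,8.552,0.079,0.056
M,M6,0.1189,8.552,0.079,0.056
M,M7,0.1220,8.552,0.079,0.056
O,O1,0.2497,5.425,0.106,0.095
O,O2,0.1221,5.425,0.106,0.095
O,O3,0.2449,5.425,0.106,0.095
O,O4,0.1836,5.425,0.106,0.095
O,O5,0.2000,5.425,0.106,0.095
N,N1,0.2879,5.441,0.110,0.098
N,N2,0.2485,5.441,0.110,0.098
N,N3,0.1250,5.441,0.110,0.098
N,N4,0.1150,5.441,0.110,0.098
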