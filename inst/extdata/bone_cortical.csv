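energy_keV,mu_over_rho_total,mu_over_rho_pe,mu_over_rho_incoh,mu_over_rho_coh,mu_en_over_rho
10,28.51,27.5239,0.108819,0.877319,26.8
12.2474,15.9955,15.2414,0.121767,0.632315,14.9933
15,9.032,8.44001,0.136255,0.455732,8.388
17.3205,5.9899,5.4893,0.143254,0.35735,5.49592
20,4.001,3.57018,0.150612,0.280206,3.601
24.4949,2.2715,1.91917,0.156284,0.196047,1.96292
30,1.331,1.03166,0.16217,0.137165,1.07
34.641,0.926936,0.658054,0.1634,0.105482,0.694442
40,0.6655,0.419743,0.16464,0.0811166,0.4507
44.7214,0.524797,0.294735,0.164213,0.0658491,0.324474
50,0.424199,0.206957,0.163787,0.0534552,0.2336
54.7723,0.362187,0.154567,0.162674,0.0449464,0.180842
60,0.3148,0.11544,0.161568,0.037792,0.14
69.282,0.259711,0.0724725,0.158634,0.0286041,0.0982568
80,0.2229,0.0454979,0.155752,0.0216499,0.06896
89.4427,0.201616,0.0315728,0.152674,0.0173688,0.05623
100,0.1855,0.0219097,0.149656,0.0139343,0.04585
122.474,0.163211,0.0112273,0.14269,0.0092936,0.0382022
150,0.148,0.00575331,0.136048,0.00619847,0.03183
173.205,0.138738,0.00358822,0.130489,0.00466075,0.0309169
200,0.1309,0.0022379,0.125158,0.00350451,0.03003
244.949,0.120358,0.00113901,0.116897,0.00232154,0.0301747
300,0.1113,0.000579719,0.109182,0.00153788,0.03032
346.41,0.104955,0.000366907,0.103415,0.00117347,0.0305044
400,0.09908,0.000232217,0.0979524,0.000895408,0.03069
447.214,0.0945303,0.00016453,0.0936323,0.000733436,0.03071
500,0.09022,0.000116572,0.0895027,0.000600763,0.03073
547.723,0.0866942,8.7203e-05,0.086101,0.000505951,0.0306248
600,0.08332,6.52332e-05,0.0828287,0.000426102,0.03052
692.82,0.0780246,4.28039e-05,0.0776447,0.000337084,0.0301224
800,0.0730799,2.80866e-05,0.0727852,0.000266663,0.02973
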