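energy_keV,mu_over_rho_total,mu_over_rho_pe,mu_over_rho_incoh,mu_over_rho_coh,mu_en_over_rho
10,5.329,4.73877,0.142544,0.44769,4.944
12.2474,2.9398,2.48069,0.15408,0.305032,2.60635
15,1.673,1.29862,0.16655,0.207832,1.374
17.3205,1.14552,0.816226,0.171808,0.15749,0.869547
20,0.809599,0.513026,0.177232,0.119341,0.5503
24.4949,0.526593,0.265663,0.180496,0.0804344,0.292714
30,0.3756,0.137569,0.183819,0.0542116,0.1557
34.641,0.310716,0.0861549,0.183629,0.0409318,0.104002
40,0.2683,0.0539558,0.183439,0.030905,0.06947
44.7214,0.244506,0.0375389,0.182109,0.0248579,0.0541638
50,0.2269,0.0261172,0.180789,0.019994,0.04223
54.7723,0.215285,0.0194619,0.179049,0.0167736,0.0367034
60,0.2059,0.0145026,0.177325,0.014072,0.0319
69.282,0.193354,0.00912664,0.173551,0.0106765,0.0287827
80,0.1837,0.00574349,0.169856,0.00810039,0.02597
89.4427,0.176743,0.00399987,0.166221,0.00652179,0.0257137
100,0.1707,0.00278558,0.162664,0.00525083,0.02546
122.474,0.159822,0.00145429,0.1548,0.00356799,0.0265276
150,0.1505,0.000759256,0.147316,0.00242448,0.02764
173.205,0.143498,0.000476215,0.141188,0.00183335,0.028637
200,0.137,0.000298689,0.135315,0.00138634,0.02967
244.949,0.12739,0.000154252,0.126304,0.000931839,0.0307744
300,0.1186,7.96601e-05,0.117894,0.000626342,0.03192
346.41,0.112159,4.97603e-05,0.111638,0.000471697,0.0323521
400,0.1061,3.10831e-05,0.105714,0.000355234,0.03279
447.214,0.101379,2.39782e-05,0.101038,0.00031681,0.0328898
500,0.09687,1.84974e-05,0.096569,0.000282542,0.03299
547.723,0.0931404,1.36763e-05,0.0928915,0.000235186,0.0329149
600,0.08956,1.01118e-05,0.0893541,0.000195767,0.03284
692.82,0.0839267,7.06568e-06,0.0837547,0.00016492,0.0324477
800,0.07865,4.93717e-06,0.0785061,0.000138934,0.03206
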