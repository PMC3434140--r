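energy_keV,mu_over_rho_total,mu_over_rho_pe,mu_over_rho_incoh,mu_over_rho_coh,mu_en_over_rho
10,5.44984,4.85651,0.141363,0.451972,5.06206
12.2474,3.00308,2.54233,0.152803,0.307949,2.66494
15,1.70587,1.33088,0.16517,0.20982,1.40296
17.3205,1.16589,0.836506,0.170384,0.158996,0.885813
20,0.82202,0.525773,0.175764,0.120483,0.559291
24.4949,0.532467,0.272263,0.179,0.0812037,0.295965
30,0.378013,0.140987,0.182296,0.0547301,0.156618
34.641,0.311726,0.0882955,0.182107,0.0413233,0.104269
40,0.268416,0.0552964,0.181919,0.0312006,0.0694174
44.7214,0.244167,0.0384716,0.1806,0.0250956,0.0540321
50,0.226242,0.0267661,0.179291,0.0201852,0.0420567
54.7723,0.214445,0.0199455,0.177565,0.0169341,0.0365219
60,0.204926,0.0148629,0.175856,0.0142066,0.0317155
69.282,0.192244,0.00935341,0.172112,0.0107787,0.0285958
80,0.182513,0.0058862,0.168449,0.00817786,0.0257829
89.4427,0.175526,0.00409925,0.164843,0.00658417,0.0255217
100,0.169472,0.00285479,0.161316,0.00530105,0.0252632
122.474,0.15861,0.00149043,0.153517,0.00360212,0.0263174
150,0.149321,0.00077812,0.146095,0.00244767,0.0274156
173.205,0.142357,0.000488047,0.140018,0.00185088,0.0284032
200,0.1359,0.00030611,0.134194,0.0013996,0.0294263
244.949,0.126357,0.000158084,0.125258,0.000940751,0.0305209
300,0.117631,8.16394e-05,0.116917,0.000632332,0.0316562
346.41,0.11124,5.09966e-05,0.110713,0.000476208,0.0320845
400,0.105228,3.18554e-05,0.104838,0.000358632,0.0325186
447.214,0.100545,2.4574e-05,0.100201,0.00031984,0.0326176
500,0.0960729,1.8957e-05,0.0957687,0.000285245,0.0327168
547.723,0.0923732,1.40161e-05,0.0921217,0.000237435,0.0326423
600,0.0888216,1.03631e-05,0.0886136,0.000197639,0.032568
692.82,0.0832343,7.24123e-06,0.0830606,0.000166497,0.0321789
800,0.0780008,5.05984e-06,0.0778555,0.000140263,0.0317944
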