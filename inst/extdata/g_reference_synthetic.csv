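r_cm,g,se
0.096388,1.01005,0.0037
0.105112,1.00122,0.0046
0.114626,1.00828,0.00364
0.125,1.00066,0.00269
0.136313,1.0006,0.00305
0.148651,1.0008,0.003
0.162105,0.996594,0.00267
0.176777,0.995314,0.00278
0.192776,0.996105,0.00278
0.210224,0.998009,0.00245
0.229251,0.998309,0.00273
0.25,0.995819,0.0026
0.272627,0.995414,0.00232
0.297302,0.995143,0.0025
0.32421,0.998781,0.00254
0.353553,0.993381,0.00242
0.385553,0.993801,0.00256
0.420448,0.996796,0.00227
0.458502,0.995092,0.00242
0.5,0.995192,0.00229
0.545254,0.995443,0.00261
0.594604,0.993241,0.00251
0.64842,0.99332,0.00231
0.707107,0.994465,0.0025
0.771105,0.997331,0.00243
0.840896,0.997543,0.00255
0.917004,0.998942,0.00251
1,1,0
1.090508,0.999702,0.00256
1.189207,1.00145,0.00245
1.29684,1.00492,0.00266
1.414214,1.00314,0.00256
1.542211,1.00394,0.00241
1.681793,1.00489,0.00247
1.834008,1.00603,0.00266
2,1.00608,0.00251
2.181015,1.0053,0.0025
2.378414,1.0057,0.00243
2.593679,1.00579,0.00243
2.828427,1.00719,0.0024
3.084422,1.00896,0.00242
3.363586,1.00797,0.0026
3.668016,1.00795,0.00265
4,1.00541,0.00269
4.362031,1.0019,0.0025
4.756828,0.999608,0.00255
5.187358,0.993233,0.00252
5.656854,0.990882,0.00253
6.168843,0.980311,0.00229
6.727171,0.968838,0.00232
7.336032,0.959697,0.00242
8,0.943444,0.0022
8.724062,0.922024,0.0022
9.513657,0.897676,0.00212
10.374716,0.867028,0.00198
11.313708,0.825028,0.00195
12.152474,0.781589,0.00191
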