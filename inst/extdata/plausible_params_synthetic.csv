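"alpha","delta","tau","lambda_self","lambda_other"
0.1823,0.0539,0.03883,-0.2091,0.472
0.165,0.0319,0.00755,-0.0349,-0.3021
0.1887,0.0612,0.03664,0.2893,-0.2295
0.2013,0.0135,0.05357,-0.3196,0.2058
0.083,0.0117,0.03947,0.2746,-0.2132
0.2879,0.074,0.05008,0.0779,-0.1336
0.0672,0.0248,0.06812,0.4478,0.4034
0.1861,0.0126,0.03202,-0.0068,-0.0509
0.0601,0.0354,0.04857,0.0798,-0.2297
0.0604,0.0833,0.04397,0.3146,0.4622
0.3546,0.033,0.03733,-0.3907,0.2227
0.1478,0.0376,0.05002,0.3859,-0.3052
0.3737,0.2474,0.04342,0.0424,-0.1384
0.1704,0.0597,0.02782,0.0712,-0.1285
0.0929,0.0102,0.02087,-0.0798,-0.2338
0.1146,0.1827,0.04359,-0.0111,-0.0953
0.2786,0.0413,0.06843,-0.1754,-0.23
0.138,0.0266,0.01063,0.6175,-0.85
0.2219,0.0926,0.06173,0.0378,-0.8188
0.1657,0.0165,0.05886,0.1358,0.2575
0.1238,0.0665,0.00471,0.3263,0.1251
0.0382,0.0663,0.01086,-0.326,-0.5093
0.0908,0.1706,0.01717,0.2495,0.3758
0.3423,0.0914,0.02392,0.3919,0.4987
0.2954,0.1406,0.04117,0.1355,0.5362
0.197,0.0332,0.02776,0.2611,-0.2059
0.1063,0.0711,0.0436,-0.1621,0.2904
0.1405,0.0103,0.06521,0.4048,0.0224
0.0937,0.028,0.07482,0.5355,-0.1995
0.1225,0.0625,0.02446,-0.0221,0.4935
0.0513,0.024,0.07711,-0.0577,0.5185
0.0411,0.0241,0.05708,-0.0222,-0.3879
0.2638,0.0621,0.06941,0.6905,0.45
0.3607,0.0533,0.03371,-0.056,-0.474
0.4133,0.252,0.02754,-0.1297,-0.2456
0.1155,0.0142,0.05139,-0.0497,-0.1627
0.1322,0.0559,0.00674,0.3712,-0.2319
0.1248,0.0926,0.05331,0.1722,-0.3588
0.0711,0.1029,0.01035,-0.0176,-0.1753
0.1852,0.1404,0.07395,-0.2266,0.3403
0.1839,0.1182,0.02991,-0.075,-0.3447
0.0954,0.0334,0.0314,0.3177,-0.0638
0.2018,0.0313,0.00978,0.36,0.3228
0.1413,0.0502,0.03061,0.3378,-0.0993
0.1129,0.1221,0.03724,0.0239,-0.1753
0.1995,0.0261,0.02809,0.4143,-0.1219
0.1043,0.032,0.01067,-0.0192,0.0943
0.0517,0.0343,0.02468,0.3493,0.0343
0.0504,0.0257,0.01742,0.0013,0.0251
0.419,0.0286,0.03775,-0.0529,-0.2
0.1181,0.0103,0.06426,0.4501,-0.3515
0.1256,0.0429,0.03215,-0.0464,0.0613
0.1637,0.0565,0.01424,0.3971,-0.4366
0.1069,0.0128,0.02628,-0.0831,0.314
0.0822,0.0403,0.02384,-0.2412,0.2913
0.1763,0.0232,0.00357,0.044,0.0072
0.0282,0.0209,0.04513,0.2368,0.2639
0.2313,0.0545,0.02996,0.0731,0.2745
0.0377,0.1078,0.05439,-0.4452,-0.1007
0.1645,0.1109,0.06195,-0.2929,-0.4833
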