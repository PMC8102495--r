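pesticide,adi_mg_kg_bw_day,2-4 Male,2-4 Female,18-30 Male,18-30 Female,60-70 Male,60-70 Female
Acetamiprid,0.07,0.565,0.604,0.1259,0.1833,0.1005,0.1168
Azoxystrobin,0.2,0.082,0.0876,0.0183,0.0266,0.0146,0.017
Bifenazate,0.01,4.6923,5.0165,1.046,1.5226,0.8348,0.9703
Boscalid,0.04,1.6078,1.7188,0.3584,0.5217,0.286,0.3325
Carbendazim,0.03,1.8782,2.0079,0.4187,0.6095,0.3341,0.3884
Chlorantraniliprole,2,0.0025,0.0026,5e-4,8e-4,4e-4,5e-4
Clothianidin,0.1,0.0831,0.0888,0.0185,0.027,0.0148,0.0172
Cyantraniliprole,0.03,0.4701,0.5025,0.1048,0.1525,0.0836,0.0972
Cyhalothrin,0.02,0.2603,0.2783,0.058,0.0845,0.0463,0.0538
Cypermethrin,0.02,0.53,0.5666,0.1181,0.172,0.0943,0.1096
Cyprodinil,0.03,2.0486,2.1902,0.4567,0.6648,0.3645,0.4236
Diethyl aminoethyl hexanoate,0.023,0.2857,0.3054,0.0637,0.0927,0.0508,0.0591
Difenoconazole,0.01,5.5105,5.8913,1.2284,1.7881,0.9804,1.1395
Dimethomorph,0.2,0.0356,0.0381,0.0079,0.0116,0.0063,0.0074
Dinotefuran,0.2,0.1277,0.1365,0.0285,0.0414,0.0227,0.0264
Ethirimol,0.035,4.3045,4.6019,0.9596,1.3968,0.7658,0.8901
Etoxazole,0.05,0.1196,0.1279,0.0267,0.0388,0.0213,0.0247
Flonicamid,0.07,0.1536,0.1643,0.0342,0.0499,0.0273,0.0318
Fludioxonil,0.4,0.0416,0.0445,0.0093,0.0135,0.0074,0.0086
Fluopyram,0.01,23.4244,25.0429,5.2219,7.6011,4.1674,4.8438
Forchlorfenuron,0.07,0.0128,0.0137,0.0029,0.0042,0.0023,0.0027
Fosthiazate,0.004,2.0145,2.1537,0.4491,0.6537,0.3584,0.4166
Hexaconazole,0.005,1.2521,1.3386,0.2791,0.4063,0.2228,0.2589
Hexaflumuron,0.02,0.5904,0.6312,0.1316,0.1916,0.105,0.1221
Imazalil,0.03,0.8823,0.9432,0.1967,0.2863,0.157,0.1824
Imidacloprid,0.06,0.2164,0.2314,0.0482,0.0702,0.0385,0.0448
Indoxacarb,0.01,0.4587,0.4904,0.1023,0.1488,0.0816,0.0949
Kresoxim-methyl,0.4,0.016,0.0171,0.0036,0.0052,0.0028,0.0033
Metalaxyl,0.08,0.038,0.0406,0.0085,0.0123,0.0068,0.0079
Methoxyfenozide,0.1,0.0834,0.0891,0.0186,0.0271,0.0148,0.0172
Myclobutanil,0.03,1.3027,1.3927,0.2904,0.4227,0.2318,0.2694
Nitenpyram,0.53,0.0104,0.0111,0.0023,0.0034,0.0019,0.0022
Novaluron,0.01,0.5858,0.6262,0.1306,0.1901,0.1042,0.1211
Oxadixyl,0.01,0.5207,0.5567,0.1161,0.169,0.0926,0.1077
Paclobutrazol,0.1,0.4128,0.4413,0.092,0.134,0.0734,0.0854
Picoxystrobin,0.09,0.3196,0.3417,0.0712,0.1037,0.0569,0.0661
Prochloraz,0.01,1.0631,1.1365,0.237,0.345,0.1891,0.2198
Propamocarb,0.4,0.0231,0.0247,0.0051,0.0075,0.0041,0.0048
Pymetrozine,0.03,0.1405,0.1502,0.0313,0.0456,0.025,0.0291
Pyraclostrobin,0.03,2.592,2.7711,0.5778,0.8411,0.4611,0.536
Pyridaben,0.01,0.2417,0.2584,0.053900000000000003,0.0784,0.043,0.05
Pyrimethanil,0.2,0.378,0.4041,0.0843,0.1226,0.0672,0.0782
Pyriproxyfen,0.1,0.04,0.0427,0.0089,0.013,0.0071,0.0083
Spinetoram A,0.05,0.1035,0.1107,0.0231,0.0336,0.0184,0.0214
Spinosad A,0.02,0.1426,0.1524,0.0318,0.0463,0.0254,0.0295
Spirodiclofen,0.01,2.8266,3.0219,0.6301,0.9172,0.5029,0.5845
Spirotetramat,0.05,0.432,0.4619,0.0963,0.1402,0.0769,0.0893
Sulfoxaflor,0.05,0.4853,0.5189,0.1082,0.1575,0.0863,0.1004
Tebuconazole,0.03,0.1384,0.148,0.0309,0.0449,0.0246,0.0286
Thiacloprid,0.01,0.4928,0.5268,0.1099,0.1599,0.0877,0.1019
Thiamethoxam,0.08,0.0488,0.0522,0.0109,0.0158,0.0087,0.0101
Thiophanate-methyl,0.09,0.4525,0.4838,0.1009,0.1468,0.0805,0.0936
Triadimefon,0.03,0.124,0.1325,0.0276,0.0402,0.0221,0.0256
Triadimenol,0.03,0.8037,0.8593,0.1792,0.2608,0.143,0.1662
Trichlorfon,0.002,1.1467,1.226,0.2556,0.3721,0.204,0.2371
Trifloxystrobin,0.04,0.7462,0.7977,0.1663,0.2421,0.1327,0.1543
Triflumuron,0.014,10.3605,11.0763,2.3096,3.3619,1.8432,2.1424
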