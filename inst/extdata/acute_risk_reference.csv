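pesticide,arfd_mg_kg_bw_day,2-4 Male,2-4 Female,18-30 Male,18-30 Female,60-70 Male,60-70 Female
Acetamiprid,0.1,9.9507,10.4705,3.4861,4.0097,3.4406,3.8842
Carbendazim,0.5,4.7391,4.9866,1.6603,1.9097,1.6386,1.8499
Clothianidin,0.6,0.3546,0.3731,0.1242,0.1429,0.1226,0.1384
Cyhalothrin,0.02,7.7869,8.1937,2.7281,3.1378,2.6925,3.0396
Cypermethrin,0.04,4.2545,4.4768,1.4905,1.7144,1.4711,1.6607
Difenoconazole,0.3,5.889,6.1966,2.0631,2.373,2.0362,2.2987
Dimethomorph,0.6,0.1356,0.1427,0.0475,0.0546,0.0469,0.0529
Dinotefuran,1,0.4005,0.4214,0.1403,0.1614,0.1385,0.1563
Fluopyram,0.5,32.6272,34.3316,11.4307,13.1474,11.2815,12.7358
Imazalil,0.05,7.851,8.2611,2.7505,3.1636,2.7146,3.0646
Imidacloprid,0.4,0.9111,0.9587,0.3192,0.3671,0.315,0.3556
Indoxacarb,0.1,0.4468,0.4701,0.1565,0.18,0.1545,0.1744
Methoxyfenozide,0.9,0.087,0.0915,0.0305,0.0351,0.0301,0.034
Picoxystrobin,0.09,5.2043,5.4762,1.8233,2.0971,1.7995,2.0315
Prochloraz,0.1,2.3315,2.4533,0.8168,0.9395,0.8062,0.9101
Propamocarb,2,0.0806,0.0849,0.0283,0.0325,0.0279,0.0315
Pymetrozine,0.1,0.5445,0.573,0.1908,0.2194,0.1883,0.2125
Pyraclostrobin,0.05,51.5945,54.2898,18.0757,20.7905,17.8398,20.1396
Spirotetramat,1,0.5846,0.6151,0.2048,0.2356,0.2021,0.2282
Sulfoxaflor,0.3,1.629,1.7141,0.5707,0.6564,0.5632,0.6359
Tebuconazole,0.3,0.1282,0.1349,0.0449,0.0517,0.0443,0.05
Thiacloprid,0.03,2.9286,3.0816,1.026,1.1801,1.0126,1.1432
Thiamethoxam,1,0.0553,0.0582,0.0194,0.0223,0.0191,0.0216
Triadimefon,0.08,0.5106,0.5373,0.1789,0.2058,0.1766,0.1993
Triadimenol,0.08,2.3409,2.4632,0.8201,0.9433,0.8094,0.9138
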