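pesticide,adi_mg_kg_bw_day,arfd_mg_kg_bw_day,arfd_status
Acetamiprid,0.07,0.1,established
Azoxystrobin,0.2,,unnecessary
Bifenazate,0.01,,unnecessary
Boscalid,0.04,,unnecessary
Carbendazim,0.03,0.5,established
Chlorantraniliprole,2,,unnecessary
Clothianidin,0.1,0.6,established
Cyantraniliprole,0.03,,unnecessary
Cyhalothrin,0.02,0.02,established
Cypermethrin,0.02,0.04,established
Cyprodinil,0.03,,unnecessary
Diethyl aminoethyl hexanoate,0.023,,not_established
Difenoconazole,0.01,0.3,established
Dimethomorph,0.2,0.6,established
Dinotefuran,0.2,1,established
Ethirimol,0.035,,not_established
Etoxazole,0.05,,unnecessary
Flonicamid,0.07,,unnecessary
Fludioxonil,0.4,,unnecessary
Fluopyram,0.01,0.5,established
Forchlorfenuron,0.07,,not_established
Fosthiazate,0.004,,unnecessary
Hexaconazole,0.005,,not_established
Hexaflumuron,0.02,,not_established
Imazalil,0.03,0.05,established
Imidacloprid,0.06,0.4,established
Indoxacarb,0.01,0.1,established
Kresoxim-methyl,0.4,,unnecessary
Metalaxyl,0.08,,unnecessary
Methoxyfenozide,0.1,0.9,established
Myclobutanil,0.03,,unnecessary
Nitenpyram,0.53,,not_established
Novaluron,0.01,,unnecessary
Oxadixyl,0.01,,not_established
Paclobutrazol,0.1,,not_established
Picoxystrobin,0.09,0.09,established
Prochloraz,0.01,0.1,established
Propamocarb,0.4,2,established
Pymetrozine,0.03,0.1,established
Pyraclostrobin,0.03,0.05,established
Pyridaben,0.01,,not_established
Pyrimethanil,0.2,,unnecessary
Pyriproxyfen,0.1,,unnecessary
Spinetoram A,0.05,,unnecessary
Spinosad A,0.02,,unnecessary
Spirodiclofen,0.01,,unnecessary
Spirotetramat,0.05,1,established
Sulfoxaflor,0.05,0.3,established
Tebuconazole,0.03,0.3,established
Thiacloprid,0.01,0.03,established
Thiamethoxam,0.08,1,established
Thiophanate-methyl,0.09,,unnecessary
Triadimefon,0.03,0.08,established
Triadimenol,0.03,0.08,established
Trichlorfon,0.002,,not_established
Trifloxystrobin,0.04,,unnecessary
Triflumuron,0.014,,not_established
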