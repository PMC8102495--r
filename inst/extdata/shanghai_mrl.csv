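jurisdiction,commodity,pesticide,limit_ug_kg,basis,sum_components
CN,grape,Difenoconazole,500,standard,
CN,grape,Forchlorfenuron,50,standard,
CN,grape,Methoxyfenozide,1000,standard,
CN,grape,Picoxystrobin,1000,standard,
CN,grape,Pyraclostrobin,2000,standard,
CN,melon,Difenoconazole,700,standard,
CN,melon,Pyraclostrobin,500,standard,
CN,peach,Acetamiprid,2000,standard,
CN,peach,Carbendazim,2000,standard,
CN,peach,Clothianidin,200,standard,
CN,peach,Cyhalothrin,500,standard,
CN,peach,Cypermethrin,1000,standard,
CN,peach,Difenoconazole,500,standard,
CN,peach,Imidacloprid,500,standard,
CN,peach,Indoxacarb,1000,standard,
CN,peach,Pyraclostrobin,1000,standard,
CN,peach,Spinosad A,200,temporary,
CN,peach,Spirodiclofen,2000,standard,
CN,strawberry,Acetamiprid,2000,standard,
CN,strawberry,Azoxystrobin,10000,standard,
CN,strawberry,Bifenazate,2000,standard,
CN,strawberry,Boscalid,3000,standard,
CN,strawberry,Carbendazim,500,standard,
CN,strawberry,Chlorantraniliprole,1000,temporary,
CN,strawberry,Cyantraniliprole,4000,temporary,
CN,strawberry,Cyprodinil,2000,standard,
CN,strawberry,Dimethomorph,50,standard,
CN,strawberry,Fludioxonil,3000,standard,
CN,strawberry,Fluopyram,400,temporary,
CN,strawberry,Imazalil,2000,standard,
CN,strawberry,Kresoxim-methyl,2000,standard,
CN,strawberry,Methoxyfenozide,2000,standard,
CN,strawberry,Myclobutanil,1000,standard,
CN,strawberry,Novaluron,500,standard,
CN,strawberry,Pyraclostrobin,2000,standard,
CN,strawberry,Pyrimethanil,7000,standard,
CN,strawberry,Spirodiclofen,2000,standard,
CN,strawberry,Spirotetramat,1500,temporary,spirotetramat;spirotetramat-enol
CN,strawberry,Sulfoxaflor,500,temporary,
CN,strawberry,Thiacloprid,1000,standard,
CN,strawberry,Thiamethoxam,500,standard,
CN,strawberry,Triadimefon,700,standard,
CN,strawberry,Triadimenol,700,standard,
CN,strawberry,Trichlorfon,200,standard,
CN,strawberry,Trifloxystrobin,1000,standard,
CN,watermelon,Acetamiprid,200,standard,
CN,watermelon,Dinotefuran,1000,standard,
CN,watermelon,Pyraclostrobin,500,standard,
EU,grape,Difenoconazole,3000,standard,
EU,grape,Ethirimol,500,standard,
EU,grape,Forchlorfenuron,10,analytical_determination_default,
EU,grape,Methoxyfenozide,1000,standard,
EU,grape,Picoxystrobin,10,analytical_determination_default,
EU,grape,Pyraclostrobin,1000,standard,
EU,grape,Triflumuron,10,analytical_determination_default,
EU,melon,Azoxystrobin,1000,standard,
EU,melon,Difenoconazole,200,standard,
EU,melon,Ethirimol,80,standard,
EU,melon,Fluopyram,400,standard,
EU,melon,Fosthiazate,20,analytical_determination_default,
EU,melon,Indoxacarb,500,standard,
EU,melon,Paclobutrazol,10,analytical_determination_default,
EU,melon,Pyraclostrobin,500,standard,
EU,melon,Thiamethoxam,150,standard,
EU,melon,Trifloxystrobin,300,standard,
EU,peach,Acetamiprid,200,standard,
EU,peach,Carbendazim,200,standard,
EU,peach,Clothianidin,150,standard,
EU,peach,Cyhalothrin,150,standard,
EU,peach,Cypermethrin,2000,standard,
EU,peach,Difenoconazole,500,standard,
EU,peach,Imidacloprid,500,standard,
EU,peach,Indoxacarb,1000,standard,
EU,peach,Paclobutrazol,150,standard,
EU,peach,Pymetrozine,30,standard,
EU,peach,Pyraclostrobin,300,standard,
EU,peach,Pyridaben,300,standard,
EU,peach,Pyriproxyfen,500,standard,
EU,peach,Spinosad A,600,standard,
EU,peach,Spirodiclofen,2000,standard,
EU,peach,Thiophanate-methyl,2000,standard,
EU,strawberry,Acetamiprid,5000,standard,
EU,strawberry,Azoxystrobin,10000,standard,
EU,strawberry,Bifenazate,3000,standard,
EU,strawberry,Boscalid,6000,standard,
EU,strawberry,Carbendazim,100,analytical_determination_default,
EU,strawberry,Chlorantraniliprole,1000,standard,
EU,strawberry,Cyantraniliprole,1500,standard,
EU,strawberry,Cyprodinil,5000,standard,
EU,strawberry,Difenoconazole,2000,standard,
EU,strawberry,Dimethomorph,700,standard,
EU,strawberry,Ethirimol,200,standard,
EU,strawberry,Etoxazole,200,standard,
EU,strawberry,Flonicamid,30,analytical_determination_default,
EU,strawberry,Fludioxonil,4000,standard,
EU,strawberry,Fluopyram,2000,standard,
EU,strawberry,Hexaconazole,10,analytical_determination_default,
EU,strawberry,Imazalil,2000,standard,
EU,strawberry,Indoxacarb,600,standard,
EU,strawberry,Kresoxim-methyl,1500,standard,
EU,strawberry,Metalaxyl,600,standard,
EU,strawberry,Methoxyfenozide,2000,standard,
EU,strawberry,Myclobutanil,1000,standard,
EU,strawberry,Novaluron,500,standard,
EU,strawberry,Oxadixyl,10,analytical_determination_default,
EU,strawberry,Prochloraz,30,analytical_determination_default,
EU,strawberry,Propamocarb,10,analytical_determination_default,
EU,strawberry,Pyraclostrobin,1500,standard,
EU,strawberry,Pyrimethanil,5000,standard,
EU,strawberry,Pyriproxyfen,50,analytical_determination_default,
EU,strawberry,Spinetoram A,200,standard,
EU,strawberry,Spirodiclofen,2000,standard,
EU,strawberry,Spirotetramat,4000,standard,spirotetramat;spirotetramat-enol
EU,strawberry,Sulfoxaflor,500,standard,
EU,strawberry,Tebuconazole,20,analytical_determination_default,
EU,strawberry,Thiacloprid,1000,standard,
EU,strawberry,Thiamethoxam,300,standard,
EU,strawberry,Thiophanate-methyl,100,analytical_determination_default,
EU,strawberry,Triadimefon,10,analytical_determination_default,
EU,strawberry,Triadimenol,500,standard,
EU,strawberry,Trichlorfon,10,analytical_determination_default,
EU,strawberry,Trifloxystrobin,1000,standard,
EU,watermelon,Acetamiprid,200,standard,
EU,watermelon,Clothianidin,20,analytical_determination_default,
EU,watermelon,Ethirimol,80,standard,
EU,watermelon,Etoxazole,50,standard,
EU,watermelon,Methoxyfenozide,10,analytical_determination_default,
EU,watermelon,Oxadixyl,10,analytical_determination_default,
EU,watermelon,Pymetrozine,300,standard,
EU,watermelon,Pyraclostrobin,500,standard,
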