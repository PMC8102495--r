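commodity,pesticide,n_samples,n_detects_assumed,min_ug_kg,max_ug_kg,mean_ug_kg,cn_exceed,eu_exceed
strawberry,Acetamiprid,80,6,4.6,87.2,19.9,0,0
strawberry,Azoxystrobin,80,5,4.1,148.3,40.1,0,0
strawberry,Bifenazate,80,5,32.2,540.1,151.4,0,0
strawberry,Boscalid,80,9,4.5,1823.8,207.5,0,0
strawberry,Carbendazim,80,8,3.4,294.8,58.5,0,2
strawberry,Chlorantraniliprole,80,5,8.6,38.5,15.9,0,0
strawberry,Cyantraniliprole,80,3,18.7,69.6,45.5,0,0
strawberry,Cyprodinil,80,4,3.8,624.5,198.3,0,0
strawberry,Diethyl aminoethyl hexanoate,80,3,20,22.8,21.2,,
strawberry,Difenoconazole,80,8,5.3,167.6,28.1,,0
strawberry,Dimethomorph,80,3,12.3,33.8,23,0,0
strawberry,Dinotefuran,80,2,5.8,44.6,25.2,,
strawberry,Ethirimol,80,12,5.6,665.2,131.1,,5
strawberry,Etoxazole,80,3,4.9,29.9,15.8,,0
strawberry,Flonicamid,80,14,5,126.9,34.7,,12
strawberry,Fludioxonil,80,6,9.3,248.4,53.7,0,0
strawberry,Fluopyram,80,30,3.3,6260.5,544.9,13,4
strawberry,Hexaconazole,80,2,15.6,24.7,20.2,,2
strawberry,Imazalil,80,3,7.8,163.1,85.4,0,0
strawberry,Indoxacarb,80,3,4,7.5,5.9,,0
strawberry,Kresoxim-methyl,80,4,7.9,58.4,20.6,0,0
strawberry,Metalaxyl,80,4,6.3,11.5,9.8,,0
strawberry,Methoxyfenozide,80,2,7.2,7.4,7.3,0,0
strawberry,Myclobutanil,80,4,9.3,447.2,126.1,0,0
strawberry,Nitenpyram,80,2,4.9,15.3,10.1,,
strawberry,Novaluron,80,3,11,26.7,18.9,0,0
strawberry,Oxadixyl,80,2,3.5,7.1,5.3,,0
strawberry,Prochloraz,80,5,6.1,96.9,34.3,,2
strawberry,Propamocarb,80,4,3.8,67,29.8,,3
strawberry,Pyraclostrobin,80,9,3.6,681.8,82.5,0,0
strawberry,Pyrimethanil,80,10,6.8,2193.3,243.9,0,0
strawberry,Pyriproxyfen,80,1,7.7,7.7,7.7,,0
strawberry,Spinetoram A,80,3,10.8,20.3,16.7,,0
strawberry,Spirodiclofen,80,1,11.9,11.9,11.9,0,0
strawberry,Spirotetramat,80,4,8.3,242.9,69.7,0,0
strawberry,Sulfoxaflor,80,3,12,203,78.3,0,0
strawberry,Tebuconazole,80,3,12,16,13.4,,0
strawberry,Thiacloprid,80,3,4.5,36.5,15.9,0,0
strawberry,Thiamethoxam,80,4,3.8,17.1,8.2,0,0
strawberry,Thiophanate-methyl,80,12,6.8,1124.5,112.4,,2
strawberry,Triadimefon,80,2,7.1,17,12,0,1
strawberry,Triadimenol,80,1,77.8,77.8,77.8,0,0
strawberry,Trichlorfon,80,1,7.4,7.4,7.4,0,0
strawberry,Trifloxystrobin,80,8,3.4,672.4,88.3,0,0
watermelon,Acetamiprid,50,3,3.6,32,18.1,0,0
watermelon,Clothianidin,50,3,2.3,13.9,7.7,,0
watermelon,Dinotefuran,50,3,15.3,121.8,57.2,0,
watermelon,Ethirimol,50,3,2.4,54.6,21.4,,0
watermelon,Etoxazole,50,3,2.5,4.4,3.5,,0
watermelon,Methoxyfenozide,50,5,6.5,15.2,9.7,,3
watermelon,Nitenpyram,50,5,2.3,7.2,3.5,,
watermelon,Oxadixyl,50,7,5.8,19.2,11.5,,6
watermelon,Pymetrozine,50,3,3.6,8.9,5.9,,0
watermelon,Pyraclostrobin,50,1,2.7,2.7,2.7,0,0
melon,Azoxystrobin,50,3,2.1,27.6,12.8,,0
melon,Difenoconazole,50,3,3.9,12.1,6.8,0,0
melon,Ethirimol,50,3,7.3,49.9,24.4,,0
melon,Fluopyram,50,7,7.2,516.8,210.9,,3
melon,Fosthiazate,50,12,3.1,88.7,26,,11
melon,Indoxacarb,50,3,3.3,6.8,4.6,,0
melon,Paclobutrazol,50,3,4,10.9,8.3,,1
melon,Pyraclostrobin,50,4,2.6,26.4,9.9,0,0
melon,Thiamethoxam,50,3,3.3,5.9,4.4,,0
melon,Trifloxystrobin,50,3,3.3,11.4,8,,0
peach,Acetamiprid,40,7,18.4,294.2,89.6,0,2
peach,Carbendazim,40,10,4.8,689.6,123.3,0,3
peach,Clothianidin,40,5,2.9,74.5,19.1,0,0
peach,Cyhalothrin,40,6,6.9,64.7,16.8,0,0
peach,Cypermethrin,40,3,15.2,70.7,34.2,0,0
peach,Difenoconazole,40,5,3.3,146.3,36.6,0,0
peach,Hexaflumuron,40,4,10.8,118.1,38.1,,
peach,Imidacloprid,40,4,3.3,151.4,41.9,0,0
peach,Indoxacarb,40,1,4.3,4.3,4.3,0,0
peach,Nitenpyram,40,1,4.2,4.2,4.2,,
peach,Paclobutrazol,40,5,4.3,281.8,124.9,,3
peach,Pymetrozine,40,3,4.4,13.7,7.7,,0
peach,Pyraclostrobin,40,3,2.4,4.6,3.3,0,0
peach,Pyridaben,40,1,7.8,7.8,7.8,,0
peach,Pyriproxyfen,40,3,3,7.5,5.2,,0
peach,Spinosad A,40,1,9.2,9.2,9.2,0,0
peach,Spirodiclofen,40,5,12.1,290.6,79.3,0,0
peach,Thiophanate-methyl,40,4,7.1,50.2,19,,0
grape,Difenoconazole,40,5,11.1,408,106.3,0,0
grape,Ethirimol,40,5,71,677.1,309.2,,2
grape,Forchlorfenuron,40,3,2.3,3.8,2.9,0,0
grape,Methoxyfenozide,40,1,9.9,9.9,9.9,0,0
grape,Picoxystrobin,40,4,4.4,194.6,92.8,0,3
grape,Pyraclostrobin,40,3,31.3,356.2,152.5,0,0
grape,Triflumuron,40,40,12.9,1619.7,468,,40
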