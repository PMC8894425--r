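region,context,gene,frac_pct,numerator,denominator,mcom,mcam,diff
chr7:27147589-27148389,intragenic,HOXA3,83.3,75,90,29.0,78.7,49.7
chr7:27146069-27146600,intragenic,HOXA3,82.2,74,90,26.0,74.0,48.0
chr19:49669275-49669552,intragenic,TRPM4,81.1,73,90,24.2,73.7,49.5
chr2:54086776-54087266,promoter,GPR75-ASB3,80.0,72,90,23.9,74.3,50.3
chr1:200010625-200010832,intragenic,NR5A2,78.9,71,90,9.1,57.7,48.7
chr13:28498226-28499046,intragenic,PDX1,72.2,65,90,9.1,55.0,45.9
chr5:140857864-140858065,intragenic,PCDHGA2,72.2,65,90,17.3,62.8,45.5
chr7:27182613-27185562,promoter,HOXA-AS3,71.1,64,90,21.4,62.6,41.2
chr19:48918115-48918340,intragenic,GRIN2D,69.9,58,83,10.7,53.1,46.2
chr5:140864527-140864748,promoter,PCDHGA2,68.9,62,90,9.1,52.3,43.1
chr5:134363092-134365146,intragenic,PITX1,67.8,61,90,21.5,59.8,38.3
chr7:158936507-158938492,promoter,VIPR2,65.6,59,90,12.4,50.1,37.7
chr6:62995855-62996228,promoter,KHDRBS2,63.3,57,90,11.7,51.3,39.6
chr6:10398573-10398812,intragenic,TFAP2A,63.3,57,90,16.1,53.0,36.9
chr7:27143181-27143479,intergenic,NA,63.3,57,90,26.0,62.6,36.7
chr7:24323558-24325080,promoter,NPY,63.3,57,90,16.5,52.7,36.2
chr8:97171805-97172022,promoter,GDF6,63.3,57,90,19.8,53.5,33.7
chr13:53313127-53314045,promoter,CNMD,62.2,56,90,15.6,50.9,35.3
chrX:142721410-142722958,promoter,SLITRK4,60.7,54,89,19.2,54.8,35.5
chr7:155255098-155255311,intragenic,EN2,60.0,54,90,17.0,52.2,35.2
chr13:102568425-102569495,promoter,FGF14,60.0,54,90,15.6,50.6,35.0
chrX:66766037-66766279,intragenic,AR,58.9,53,90,20.3,55.8,35.5
chr9:37002489-37002957,promoter,PAX5,58.9,53,90,22.1,56.3,34.1
chrX:101906001-101907017,promoter,ARMCX5-GPRASP2,57.8,52,90,21.6,58.2,36.6
chr4:111549879-111550203,intragenic,PITX2,57.8,52,90,22.9,53.7,30.8
chr4:4864456-4864834,intragenic,MSX1,57.3,51,89,29.7,64.3,35.3
chr8:72753874-72754755,promoter,MSC,56.7,51,90,26.7,58.7,32.0
chr19:46915311-46915802,intragenic,CCDC8,55.6,50,90,17.7,52.1,34.5
chr8:130995921-130996149,intragenic,FAM49B,54.4,49,90,20.9,53.1,32.1
chr2:98962873-98964187,promoter,CNGA3,54.4,49,90,19.6,51.7,32.1
chr2:5836068-5837643,intragenic,SOX11,54.4,49,90,20.8,51.7,30.9
chr11:65359292-65360328,intragenic,EHBP1L1,53.3,48,90,26.6,58.0,31.4
chr6:108495654-108495986,intragenic,NR2E1,53.3,48,90,21.5,52.0,30.5
chr1:120905971-120906396,promoter,HIST2H2BA (H2BP1),53.3,48,90,28.8,59.1,30.3
chr13:70681732-70682219,promoter,KLHL1,50.0,45,90,25.1,55.5,30.4
chr16:87441387-87441671,intragenic,ZCCHC14,78.9,71,90,77.98,28.81,-49.17
chr7:5342299-5342599,intragenic,SLC29A4,77.8,70,90,73.15,26.40,-46.75
chr20:33762403-33762774,intragenic,PROCR,66.7,60,90,68.94,29.90,-39.04
chr1:235805318-235805771,intragenic,GNG4,56.7,51,90,62.69,29.03,-33.66
chr2:233925091-233925318,promoter,INPP5D,57.8,52,90,52.94,20.31,-32.63
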