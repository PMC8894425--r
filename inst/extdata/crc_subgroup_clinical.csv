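parameter,category,group1,group2
sex,male,13,39
sex,female,12,22
stage,I,0,1
stage,II,2,0
stage,III,5,48
stage,IV,18,12
lymphatic,yes,14,19
lymphatic,no,11,42
vascular,yes,11,8
vascular,no,14,53
perineural,yes,20,31
perineural,no,5,30
differentiation,well,0,1
differentiation,moderate,22,54
differentiation,poor,2,3
microsatellite,stable,21,54
microsatellite,instable_low,1,3
microsatellite,instable_high,1,3
site,ascending,5,15
site,descending,1,0
site,transverse,1,1
site,sigmoid,10,21
site,rectal,4,12
site,rectosigmoid,4,9
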