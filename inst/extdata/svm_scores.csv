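dataset,direction,ALL,IG,Chis,Pearson,PSO,GA,ACA,IG-PSO,IG-GA,IG-ACA,Chis-PSO,Pearson-PSO,IG-GPSO
Prostate-GE_ACC,higher_better,91.2,94.1,93.1,91.2,96.1,92.2,93.1,98,97.1,98,98,95.1,98
TOX-171_ACC,higher_better,95.9,97.7,97.7,98.8,99.4,100,98.8,100,98.8,100,100,100,100
GLIOMA_ACC,higher_better,76,82,82,82,84,84,82,90,88,90,95,84,96
Lung-discrete_ACC,higher_better,89,89,91.8,89,94.5,93.2,95.9,97.3,94.5,98.6,94.5,94.5,100
Prostate-GE_FS,lower_better,5966,677,677,2983,2525,2927,2380,283,331,285,130,1141,63
TOX-171_FS,lower_better,5748,769,769,2874,1732,2325,2314,338,388,364,363,1198,305
GLIOMA_FS,lower_better,4434,1398,1398,2217,1561,1856,2010,426,590,530,317,1076,138
Lung-discrete_FS,lower_better,325,111,111,163,142,153,139,52,48,53,50,59,77
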