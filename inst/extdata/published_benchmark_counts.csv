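environment,k,RP,RN,TP,FP,TN,FN,sensitivity,precision,accuracy,fpr,fdr
controlled,3,124,412,113,4,343,11,91,97,85,1,3
controlled,5,124,412,114,2,361,10,92,98,89,1,2
controlled,7,124,412,118,1,376,6,95,99,92,0,1
controlled,9,124,412,112,0,382,12,90,100,92,0,0
controlled,11,124,412,110,0,386,14,89,100,93,0,0
controlled,13,124,412,103,0,379,21,83,100,90,0,0
controlled,15,124,412,100,0,385,24,81,100,90,0,0
controlled,17,124,412,103,0,384,21,83,100,91,0,0
controlled,19,124,412,101,1,377,23,81,99,89,0,1
controlled,21,124,412,106,1,380,18,85,99,91,0,1
natural,3,29,0,23,2,0,6,79,92,79,NA,NA
natural,5,29,0,23,3,0,6,79,88,79,NA,NA
natural,7,29,0,19,1,0,10,66,95,66,NA,NA
natural,9,29,0,20,1,0,9,69,95,69,NA,NA
natural,11,29,0,19,0,0,10,66,100,66,NA,NA
natural,13,29,0,15,17,0,14,52,47,52,NA,NA
natural,15,29,0,16,1,0,13,55,94,55,NA,NA
natural,17,29,0,16,0,0,13,55,100,55,NA,NA
natural,19,29,0,15,0,0,14,52,100,52,NA,NA
natural,21,29,0,14,10,0,15,48,58,48,NA,NA
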