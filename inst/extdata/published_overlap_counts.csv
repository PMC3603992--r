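category,n_codes,area_eo,area_f1,area_f2
shared_all,19,13216,16754,8124
eo_and_f1_only,11,6177,2002,NA
eo_and_f2_only,2,3176,NA,5
eo_only,51,39735,NA,NA
novel_f1_only,18,NA,327,NA
novel_f2_only,34,NA,NA,4494
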