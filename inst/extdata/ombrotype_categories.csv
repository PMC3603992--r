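alpha,numeric,label,lower,upper
UARI,5,Upper arid,0.6,1
LSAR,6,Lower semiarid,1.01,1.5
USAR,7,Upper semiarid,1.51,2
LDRY,8,Lower dry,2.01,2.8
UDRY,9,Upper dry,2.81,3.6
LSHU,10,Lower subhumid,3.61,4.8
USHU,11,Upper subhumid,4.81,6
LHUM,12,Lower humid,6.01,9
UHUM,13,Upper humid,9.01,12
LHHU,14,Lower hyperhumid,12.01,18
UHHU,15,Upper hyperhumid,18.01,24
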