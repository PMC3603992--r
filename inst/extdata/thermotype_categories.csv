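alpha,numeric,label,lower,upper,tp_lower,tp_upper
Lsme,1,Lower supramediterranean,145,210,1200,1500
Umme,2,Upper mesomediterranean,211,280,1501,1825
Lmme,3,Lower mesomediterranean,281,350,1826,2150
Utme,4,Upper thermomediterranean,351,400,2151,2300
Ltme,5,Lower thermomediterranean,401,450,2301,2450
Uime,6,Upper inframediterranean,451,515,2451,2650
Lime,7,Lower inframediterranean,516,580,2651,Inf
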