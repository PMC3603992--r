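alpha,numeric,label,lower,upper
Exho,1,Extremely Hyperoceanic,0,4
Euho,2,Euhyperoceanic,4.01,8
Bhoc,3,Barely Hyperoceanic,8.01,11
Seho,4,Semihyperoceanic,11.01,13
Euoc,5,Euoceanic,13.01,17
Seco,6,Semicontinental,17.01,21
Suco,7,Subcontinental,21.01,28
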