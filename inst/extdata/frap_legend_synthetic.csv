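code,label,tag
1,AD.SCRB,natural
2,BO.PINE,natural
3,BO.WOOD,natural
4,C.SCRB,natural
5,CCP.CYP,natural
6,CO.WOOD,natural
7,CR.CHP,natural
8,D.FIR,natural
9,D.SCRB,natural
10,J.PINE,natural
11,JUNIPR,natural
12,KM.CON,natural
13,M.CHP,natural
14,M.WOOD,natural
15,MH.CON,natural
16,MX.CHP,natural
17,P.GRSS,natural
18,P.PINE,natural
19,R.FIR,natural
20,RDWD,natural
21,SM.CON,natural
22,VO.WOOD,natural
23,W.FIR,natural
24,URBAN,anthropogenic
25,AGRI.CROP,anthropogenic
26,AGRI.ORCH,anthropogenic
27,PASTURE,anthropogenic
28,EUCALYPT,anthropogenic
29,RIP.FOR,hydrologic
30,RIP.SCRB,hydrologic
31,FW.WETL,hydrologic
32,SAL.WETL,hydrologic
33,WET.MDW,hydrologic
34,ESTUARY,hydrologic
35,WATER,hydrologic
36,LACUSTR,hydrologic
37,UNK.SHRB,unknown
38,UNK.CON,unknown
39,UNK.HDWD,unknown
40,UNK.HERB,unknown
41,UNCLASS,unknown
42,NO.DATA,unknown
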