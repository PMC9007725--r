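id,group,sex,high_risk_area,age,macro,dmax_mm,cavernous_invasion,ki67_pct,p53_pct,n_surgeries,aip_mutation
GH1,GH,F,No,27,Macro,22,No,2,0,1,No
GH2,GH,F,Yes,76,Macro,15,No,1,0,1,No
GH3,GH,F,No,46,Macro,10,No,2,<1,1,No
GH4,GH,M,No,NA,Macro,NA,No,NA,NA,1,No
GH5,GH,M,No,57,Macro,22.5,No,1,NA,1,No
GH7,GH,F,No,48,Macro,11,No,1,2,1,No
GH8,GH,F,No,28,Macro,18,NA,5,2,1,No
GH9,GH,F,No,22,Micro,5,No,<1,NA,1,Yes
GH10,GH,F,No,35,Macro,12,No,<1,0,1,No
GH11,GH,M,Yes,63,Macro,43,Yes,5,0,2,No
GH12,GH,M,No,57,Macro,11,Yes,<1,0,1,No
NFPA1,NFPA,F,No,46,Macro,30,Yes,3,1,1,No
NFPA5,NFPA,F,No,46,Macro,22,No,<1,NA,1,No
NFPA6,NFPA,M,No,42,Macro,30,No,NA,NA,1,No
NFPA8,NFPA,F,No,NA,Macro,NA,No,NA,NA,1,No
NFPA11,NFPA,F,Yes,55,Macro,15,No,2,NA,1,No
NFPA13,NFPA,M,No,68,Macro,30,No,2,<1,1,No
NFPA14,NFPA,F,No,70,Macro,25,No,<1,NA,1,No
NFPA16,NFPA,M,No,72,Macro,23,Yes,<1,NA,1,No
NFPA18,NFPA,M,No,40,Macro,34,Yes,1,NA,2,No
NFPA19,NFPA,F,No,36,Macro,30,Yes,1,3,3,No
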