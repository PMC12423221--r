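Day,VPD.kPa,Tair,PAR,PsiSoil
0,1.8,26.5,410,0
1,2.1,28.0,455,0
2,1.2,25.9,390,0
3,2.7,29.3,520,0
4,1.95,27.4,423,0
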