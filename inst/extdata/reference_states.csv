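node,SS0,SS1,SS2
SubmucosalDC,0,1,1
Infection,0,0,0
EpithelialCell,0,0,-1
IL1b,0,1,1
TNFa,0,1,0
IL12,0,1,1
IL8,0,0,-1
CCL2,0,0,-1
GMCSF,0,0,-1
NaiveTcell,0,1,1
Th1,0,1,1
Th2,0,0,-1
Th17,0,0,-1
Treg,0,0,-1
IFNg,0,1,1
IL2,0,1,1
IL6,0,1,1
TGFb,0,0,-1
IL4,0,0,-1
IL10,0,0,-1
IL23,0,1,1
IL17,0,1,0
IL13,0,0,-1
Neutrophil,0,1,0
ROI,0,1,1
Macrophage,0,1,1
NKcell,0,1,1
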