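drug,p,am,f,ft,t1_min,t2_h
ethanol,0.28,0.27,1.0,1.0,36,42
ethanol,0.059,0.057,1.0,1.0,4,11
gabapentin,20,20,1.0,0.97,4,11
fentanyl,0.0016,0.0014,1.1,1.5,11,13
zolpidem,0.030,0.027,1.1,1.2,17,18
methadone,0.56,0.39,1.4,1.4,18,6.7
amphetamine,0.07,0.05,1.4,1.6,7,22
amphetamine,0.16,0.10,1.6,1.6,9,5.2
methamphetamine,0.44,0.33,1.3,1.6,7,22
methamphetamine,13.0,9.3,1.4,1.6,7,5.2
methamphetamine,0.34,0.19,1.7,1.6,8,30
metoprolol,7.0,6.2,1.1,1.3,1,26
quetiapine,0.24,0.15,1.6,2.0,4,11
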