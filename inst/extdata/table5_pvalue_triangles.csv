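group_a,group_b,d,p_normal_adj,p_exact_adj,p_range
Cy0,LinRegPCR,3,1.000,1.000,1.000
Cy0,Standard-Cq,3,1.000,1.000,1.000
Cy0,PCR-Miner,10,1.000,1.000,0.993
Cy0,MAK2,11,1.000,1.000,0.985
Cy0,LRE-E100,15,1.000,1.000,0.883
Cy0,5PSM,25,0.423,0.350,0.216
Cy0,DART,27,0.220,0.150,0.130
Cy0,FPLM,29,0.110,0.057,0.073
Cy0,LRE-Emax,31,0.052,0.018,0.038
Cy0,FPK-PCR,33,0.024,0.005,0.019
LinRegPCR,Standard-Cq,0,1.000,1.000,1.000
LinRegPCR,PCR-Miner,7,1.000,1.000,1.000
LinRegPCR,MAK2,8,1.000,1.000,0.999
LinRegPCR,LRE-E100,12,1.000,1.000,0.972
LinRegPCR,5PSM,22,1.000,1.000,0.403
LinRegPCR,DART,24,0.578,0.514,0.271
LinRegPCR,FPLM,26,0.307,0.232,0.169
LinRegPCR,LRE-Emax,28,0.156,0.094,0.098
LinRegPCR,FPK-PCR,30,0.076,0.033,0.053
Standard-Cq,PCR-Miner,7,1.000,1.000,1.000
Standard-Cq,MAK2,8,1.000,1.000,0.999
Standard-Cq,LRE-E100,12,1.000,1.000,0.972
Standard-Cq,5PSM,22,1.000,1.000,0.403
Standard-Cq,DART,24,0.578,0.514,0.271
Standard-Cq,FPLM,26,0.307,0.232,0.169
Standard-Cq,LRE-Emax,28,0.156,0.094,0.098
Standard-Cq,FPK-PCR,30,0.076,0.033,0.053
PCR-Miner,MAK2,1,1.000,1.000,1.000
PCR-Miner,LRE-E100,5,1.000,1.000,1.000
PCR-Miner,5PSM,15,1.000,1.000,0.883
PCR-Miner,DART,17,1.000,1.000,0.773
PCR-Miner,FPLM,19,1.000,1.000,0.631
PCR-Miner,LRE-Emax,21,1.000,1.000,0.477
PCR-Miner,FPK-PCR,23,0.782,0.738,0.334
MAK2,LRE-E100,4,1.000,1.000,1.000
MAK2,5PSM,14,1.000,1.000,0.923
MAK2,DART,16,1.000,1.000,0.833
MAK2,FPLM,18,1.000,1.000,0.705
MAK2,LRE-Emax,20,1.000,1.000,0.554
MAK2,FPK-PCR,22,1.000,1.000,0.403
LRE-E100,5PSM,10,1.000,1.000,0.993
LRE-E100,DART,12,1.000,1.000,0.972
LRE-E100,FPLM,14,1.000,1.000,0.923
LRE-E100,LRE-Emax,16,1.000,1.000,0.833
LRE-E100,FPK-PCR,18,1.000,1.000,0.705
5PSM,DART,2,1.000,1.000,1.000
5PSM,FPLM,4,1.000,1.000,1.000
5PSM,LRE-Emax,6,1.000,1.000,1.000
5PSM,FPK-PCR,8,1.000,1.000,0.999
DART,FPLM,2,1.000,1.000,1.000
DART,LRE-Emax,4,1.000,1.000,1.000
DART,FPK-PCR,6,1.000,1.000,1.000
FPLM,LRE-Emax,2,1.000,1.000,1.000
FPLM,FPK-PCR,4,1.000,1.000,1.000
LRE-Emax,FPK-PCR,2,1.000,1.000,1.000
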