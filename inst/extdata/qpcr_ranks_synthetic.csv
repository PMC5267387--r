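indicator,Cy0,LinRegPCR,Standard-Cq,PCR-Miner,MAK2,LRE-E100,5PSM,DART,FPLM,LRE-Emax,FPK-PCR
bias,1,2,3,4,5,6,7,8,9,10,11
linearity,1,2,3,4,6,5,7,8,9,10,11
precision,1,3,2,4,6,5,7,8,9,10,11
resolution,4,3,2,5,1,6,11,10,9,8,7
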