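k,n,p_exact,p_mid
5,5,0.0326,0.0440
5,10,0.0389,0.0471
5,25,0.0437,0.0489
5,50,0.0461,0.0498
5,100,0.0465,0.0490
10,5,0.0397,0.0457
10,10,0.0496,0.0543
10,25,0.0468,0.0495
10,50,0.0492,0.0512
10,100,0.0484,0.0497
25,5,0.0494,0.0521
25,10,0.0494,0.0513
25,25,0.0487,0.0498
25,50,0.0495,0.0503
25,100,0.0494,0.0499
50,5,0.0485,0.0498
50,10,0.0500,0.0509
50,25,0.0493,0.0498
50,50,0.0493,0.0497
50,100,0.0497,0.0500
100,5,0.0493,0.0500
100,10,0.0493,0.0497
100,25,0.0496,0.0498
100,50,0.0499,0.0501
100,100,0.0499,0.0500
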