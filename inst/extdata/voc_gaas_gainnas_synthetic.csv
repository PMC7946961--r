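irradiance_wm2,voc_v
0.1,0.95
1,1.07
10,1.19
100,1.31
1000,1.43
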