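irradiance_wm2,voc_v
0.1,0.38
1,0.44
10,0.5
100,0.56
1000,0.62
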