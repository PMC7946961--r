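wavelength_nm,eqe
400,0.6
425,0.68
450,0.76
475,0.805
500,0.85
525,0.875
550,0.9
575,0.91
600,0.92
625,0.925
650,0.93
675,0.935
700,0.94
725,0.94
750,0.94
775,0.94
800,0.94
825,0.93
850,0.92
875,0.91
900,0.9
925,0.865
950,0.83
975,0.765
1000,0.7
1025,0.575
1050,0.45
1075,0.315
1100,0.18
1125,0.105
1150,0.03
1175,0.015
1200,0
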