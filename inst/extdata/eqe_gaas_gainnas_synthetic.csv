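wavelength_nm,eqe
400,0.1
425,0.12
450,0.14
475,0.16
500,0.18
525,0.215
550,0.25
575,0.325
600,0.4
625,0.56
650,0.72
675,0.785
700,0.85
725,0.8575
750,0.865
775,0.8725
800,0.88
825,0.88
850,0.88
875,0.88
900,0.88
925,0.8775
950,0.875
975,0.8725
1000,0.87
1025,0.8625
1050,0.855
1075,0.8475
1100,0.84
1125,0.795
1150,0.75
1175,0.65
1200,0.55
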