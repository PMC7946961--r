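wavelength_nm,zeta
400,0.01
450,0.02
500,0.04
550,0.06
600,0.13
650,0.22
700,0.28
750,0.33
800,0.36
850,0.38
900,0.37
950,0.3
1000,0.33
1050,0.37
1100,0.36
1150,0.28
1200,0.25
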