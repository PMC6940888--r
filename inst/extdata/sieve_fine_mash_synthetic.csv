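aperture_um,mass_g
1180,4
850,9
600,22
425,28
300,20
150,12
0,5
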