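"wavelength_nm","transmittance"
400,0.08
410,0.08
420,0.08
430,0.08
440,0.0801
450,0.0802
460,0.0808
470,0.0822
480,0.0856
490,0.0926
500,0.1052
510,0.1241
520,0.1484
530,0.1735
540,0.1927
550,0.2
560,0.1927
570,0.1735
580,0.1484
590,0.1241
600,0.1052
610,0.0927
620,0.0856
630,0.0822
640,0.0809
650,0.0806
660,0.0812
670,0.084
680,0.0935
690,0.1225
700,0.1916
710,0.2884
720,0.3575
730,0.3865
740,0.396
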