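"wavelength_nm","reflectance"
400,0.09
410,0.09
420,0.09
430,0.09
440,0.09
450,0.09
460,0.0902
470,0.0907
480,0.0924
490,0.0969
500,0.1069
510,0.1252
520,0.1524
530,0.1838
540,0.2098
550,0.22
560,0.2098
570,0.1838
580,0.1524
590,0.1252
600,0.1069
610,0.0969
620,0.0924
630,0.0907
640,0.0903
650,0.0903
660,0.0911
670,0.0937
680,0.1026
690,0.1299
700,0.1946
710,0.2854
720,0.3501
730,0.3774
740,0.3863
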