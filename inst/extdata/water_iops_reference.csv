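"wavelength_nm","absorption_m1","backscatter_m1"
400,0.22153,0.0074
410,0.19064,0.007074
420,0.16393,0.006777
430,0.14256,0.006506
440,0.12429,0.006259
450,0.10929,0.006031
460,0.09657,0.005821
470,0.08615,0.005628
480,0.07743,0.005448
490,0.07226,0.00528
500,0.06835,0.005125
510,0.07192,0.004979
520,0.07642,0.004842
530,0.07472,0.004714
540,0.07372,0.004594
550,0.0773,0.00448
560,0.0814,0.004373
570,0.09483,0.004271
580,0.10864,0.004175
590,0.17073,0.004083
600,0.2331,0.003996
610,0.25816,0.003913
620,0.28343,0.003834
630,0.30917,0.003759
640,0.33507,0.003687
650,0.37355,0.003618
660,0.41215,0.003552
670,0.44014,0.003488
680,0.46822,0.003427
690,0.54727,0.003369
700,0.62639,0.003312
710,0.89855,0.003258
720,1.17077,0.003206
730,1.77602,0.003155
740,2.38131,0.003106
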