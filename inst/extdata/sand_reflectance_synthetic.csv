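"wavelength_nm","reflectance"
400,0.22
410,0.2265
420,0.233
430,0.2395
440,0.246
450,0.2525
460,0.259
470,0.2655
480,0.272
490,0.2785
500,0.285
510,0.2915
520,0.298
530,0.3045
540,0.311
550,0.3175
560,0.324
570,0.3305
580,0.337
590,0.3435
600,0.35
610,0.3565
620,0.363
630,0.3695
640,0.376
650,0.3825
660,0.389
670,0.3955
680,0.402
690,0.4085
700,0.415
710,0.4215
720,0.428
730,0.4345
740,0.441
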