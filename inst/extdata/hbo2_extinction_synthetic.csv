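wavelength_nm,extinction
400,266000
405,372933.43
410,467000
415,529993.43
420,480000
425,302516.06
430,121000
435,55376.38
440,27000
445,44908
450,62816
455,49670.54
460,33000
465,26378.04
470,20974.92
475,17334.35
480,16000
485,16471.14
490,17667.37
495,19262.91
500,20932
505,22635.85
510,24634
515,27048.15
520,30000
525,35465.09
530,43248.63
535,50216.86
540,53236
545,49415.02
550,43016
555,36523.98
560,32610
565,37928.24
570,48284.8
575,55282.49
580,50000
585,34242.68
590,18000
595,8359.97
600,3200
605,2233.31
610,1593.56
615,1192.53
620,942
625,757.96
630,614.24
635,509.4
640,442
645,397.45
650,362.18
655,336.21
660,319.6
665,308.27
670,298.84
675,292.39
680,290
685,290
690,290
695,290
700,290
705,293.97
710,304.26
715,318.42
720,334
725,353.39
730,379.51
735,410.73
740,445.41
745,481.92
750,518.61
755,553.85
760,586
765,615.93
770,645.57
775,674.9
780,703.89
785,732.53
790,760.77
795,788.61
800,816
805,843.45
810,871.21
815,898.87
820,926.06
825,952.35
830,977.37
835,1000.72
840,1022
845,1042.2
850,1062.27
855,1081.74
860,1100.15
865,1117.05
870,1131.96
875,1144.43
880,1154
885,1161.87
890,1169.5
895,1176.8
900,1183.7
905,1190.11
910,1195.94
915,1201.1
920,1205.52
925,1209.1
930,1211.77
935,1213.43
940,1214
945,1213.78
950,1213.17
955,1212.2
960,1210.94
965,1209.44
970,1207.75
975,1205.92
980,1204
985,1201.52
990,1198.15
995,1194.21
1000,1190
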