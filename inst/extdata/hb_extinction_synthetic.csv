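wavelength_nm,extinction
400,223000
405,267245.4
410,320000
415,386833.19
420,454000
425,517733.91
430,553000
435,509916.4
440,420000
445,245349.16
450,103292
455,83859.15
460,72000
465,57976.52
470,44184.89
475,33050.82
480,27000
485,24521.83
490,22580.68
495,21314.69
500,20862
505,21183.01
510,22062.87
515,23376.79
520,25000
525,28761.94
530,35094.91
535,41778.43
540,46592
545,49626.9
550,52085.07
555,53412
560,53788
565,50779.36
570,45000
575,37614.64
580,30000
585,24368.47
590,20000
595,17017.75
600,14677
605,12528.7
610,10540.97
615,8827
620,7500
625,6468.06
630,5581.04
635,4864.74
640,4345
645,3982.35
650,3697.59
655,3456.93
660,3226.56
665,2998.35
670,2786.19
675,2589.32
680,2407
685,2233.16
690,2067.65
695,1918.65
700,1794.28
705,1681.74
710,1568.95
715,1465.14
720,1379.56
725,1321.43
730,1300
735,1327.41
740,1395.93
745,1485
750,1574.07
755,1642.59
760,1670
765,1612.95
770,1476.19
775,1311.34
780,1170
785,1046.4
790,918.76
795,814.67
800,761.72
805,744.72
810,730.07
815,717.73
820,707.68
825,699.91
830,694.39
835,691.09
840,690
845,691.55
850,695.62
855,701.39
860,708
865,714.61
870,720.38
875,724.45
880,726
885,725.7
890,724.82
895,723.41
900,721.51
905,719.15
910,716.39
915,713.25
920,709.78
925,706.03
930,702.02
935,697.81
940,693.44
945,688.28
950,681.69
955,673.7
960,664.3
965,653.52
970,641.37
975,627.86
980,613
985,593.33
990,566.89
995,536.02
1000,503
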