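# Synthetic chromophore molar extinction table (decadic, cm^-1 M^-1).
# Smooth monotone-spline compilation anchored on widely used literature
# tabulations of human Hb/HbO2 molar extinction and ICG absorption in
# plasma (peak near 805 nm). Values are approximate external constants
# for simulation and unmixing, not a metrological reference; the Hb/HbO2
# isosbestic point is placed at 796 nm.
wavelength_nm,eps_Hb,eps_HbO2,eps_ICG
400,223000,140000,2000
402,244133.1,164118.1,2039.6
404,268638.6,191822.2,2078.5
406,295738.2,220422.7,2116.6
408,324653.6,247230.3,2154.1
410,354606.8,269555.4,2191
412,384819.3,284708.5,2227.3
414,414513.1,290000,2263.1
416,442909.7,283343,2298.5
418,469231.1,266372.3,2333.4
420,492698.9,241981.6,2368
422,512534.9,213064.3,2402.2
424,527960.9,182514,2436.2
426,538198.7,153224.1,2470
428,542469.9,128088.3,2503.6
430,539996.5,110000,2537
432,530000,97984.5,2570.4
434,505881.7,88829.3,2603.7
436,464767.3,82071.5,2637.1
438,411465.5,77248,2670.5
440,350784.7,73895.8,2704
442,287533.8,71552,2737.7
444,226521.2,69753.5,2771.6
446,172555.6,68037.3,2805.7
448,130445.7,65940.5,2840.2
450,105000,63000,2875
452,90598.4,59577.8,2910.2
454,78294.5,56340,2945.9
456,67907.5,53280,2982
458,59256.8,50391.1,3018.7
460,52161.5,47666.7,3056
462,46441.1,45100,3093.9
464,41914.6,42684.4,3132.5
466,38401.5,40413.3,3171.9
468,35720.9,38280,3212
470,33692.1,36277.8,3253
472,32134.4,34400,3294.8
474,30867.1,32640,3337.6
476,29709.4,30991.1,3381.4
478,28480.6,29446.7,3426.2
480,27000,28000,3472
482,25421.2,26639.7,3519
484,24016.6,25365.1,3567.1
486,22783.8,24186,3616.5
488,21720.3,23112,3667.1
490,20823.8,22152.8,3719
492,20091.7,21318,3772.3
494,19521.7,20617.3,3827
496,19111.2,20060.4,3883.1
498,18857.8,19657,3940.8
500,18759.1,19416.7,4000
502,18812.6,19349.1,4058.8
504,19015.9,19464,4115.5
506,19366.6,19771,4170.1
508,19862.1,20279.8,4222.8
510,20500,21000,4274
512,21458.1,22116.7,4323.7
514,22855.5,23753.4,4372.2
516,24601.7,25827.4,4419.6
518,26606.4,28256.2,4466.1
520,28779.2,30957.2,4512
522,31029.6,33847.7,4557.4
524,33267.3,36845,4602.5
526,35401.9,39866.7,4647.5
528,37342.9,42830,4692.6
530,39000,45652.3,4738
532,40523.7,48251.1,4783.9
534,42101.1,50543.8,4830.4
536,43696.9,52447.6,4877.8
538,45275.5,53879.9,4926.3
540,46801.7,54758.3,4976
542,48240,55000,5027.2
544,49554.9,54173.3,5079.9
546,50711.1,52139,5134.5
548,51673.2,49253.3,5191.2
550,52405.6,45872.1,5250
552,52873.1,42351.7,5311.2
554,53040.2,39048.2,5375.1
556,52864.4,36317.7,5441.7
558,52301.2,34516.2,5511.2
560,51391.6,34000,5584
562,50187.5,35210,5660.1
564,48740.8,37996.9,5739.8
566,47103.2,41831.5,5823.2
568,45326.5,46184.7,5910.5
570,43462.6,50527,6002
572,41563.2,54329.4,6097.8
574,39680.3,57062.6,6198.1
576,37865.6,58197.4,6303.1
578,36127.7,57263.7,6413
580,34255.3,54423.3,6528
582,32246.2,50065.6,6648.3
584,30140.9,44558,6774
586,27979.9,38268,6905.4
588,25803.8,31563.1,7042.7
590,23653.1,24810.8,7186
592,21568.4,18378.6,7335.6
594,19590.2,12633.9,7491.5
596,17759.1,7944.3,7654.1
598,16115.5,4677.1,7823.6
600,14700,3200,8000
602,13480.6,2771.4,8169.2
604,12391,2401.9,8319.3
606,11420.4,2087,8454
608,10558.2,1821.9,8577
610,9793.6,1602.3,8692
612,9115.7,1423.6,8802.7
614,8514,1281.1,8912.7
616,7977.6,1170.3,9025.8
618,7495.8,1086.7,9145.7
620,7057.9,1025.7,9276
622,6653.1,982.8,9420.5
624,6270.6,953.3,9582.8
626,5899.8,932.7,9766.8
628,5529.8,916.4,9975.9
630,5150,900,10214
632,4807.3,877.6,10484.7
634,4546.5,847.4,10791.8
636,4353.8,811,11138.9
638,4215.4,769.7,11529.7
640,4117.5,724.9,11968
642,4046.1,678.2,12457.4
644,3987.5,630.9,13001.6
646,3927.9,584.5,13604.3
648,3853.3,540.4,14269.2
650,3750,500,15000
652,3632.3,458.9,15785
654,3522.6,415,16610.8
656,3419.6,373.7,17478.8
658,3321.5,340.3,18390.4
660,3227,320,19346.9
662,3135.4,309.4,20349.6
664,3046.8,301,21399.9
666,2960.9,294.7,22499.2
668,2877.4,290.1,23648.8
670,2796,286.9,24850
672,2716.2,284.7,26104.2
674,2637.8,283.2,27412.8
676,2560.3,282.2,28777.1
678,2483.5,281.2,30198.4
680,2407,280,31678.1
682,2330.9,278.5,33217.6
684,2256.4,277.1,34818.2
686,2184.4,276,36481.2
688,2115.9,275.5,38208
690,2052,276,40000
692,1992.1,277.3,42040
694,1935.5,279.3,44410
696,1883.1,282,46960
698,1835.7,285.6,49540
700,1794,290,52000
702,1757.3,295.2,54331.5
704,1724,301.1,56632
706,1693.7,307.4,58910.5
708,1666.1,314.2,61176
710,1641,321.4,63437.5
712,1617.9,328.8,65704
714,1596.6,336.5,67984.5
716,1576.8,344.3,70288
718,1558,352.2,72623.5
720,1540,360,75000
722,1523.6,367.7,77413.4
724,1509.7,375.2,79852
726,1497.7,382.8,82313.6
728,1487.5,390.5,84796
730,1478.5,398.4,87296.9
732,1470.4,406.7,89814
734,1462.9,415.4,92345.1
736,1455.6,424.8,94888
738,1448.1,435,97440.4
740,1440,446,1e+05
742,1429.2,458.8,102565.8
744,1416.4,473.6,105140.6
746,1405.6,489.2,107728.5
748,1400.5,504.3,110333.3
750,1405,518,112959
752,1425.4,528.7,115609.4
754,1457.5,538.1,118288.4
756,1490,550,121000
758,1528.7,567.8,123792
760,1549,586,126689.8
762,1534,600.8,129664.1
764,1506,615,132685.2
766,1467.4,628.5,135723.7
768,1420.6,641.4,138750
770,1367.9,653.8,141734.7
772,1311.8,665.7,144648.1
774,1254.5,677.2,147460.9
776,1198.6,688.4,150143.5
778,1146.3,699.3,152666.4
780,1100,710,155000
782,1056.4,719.6,157152.1
784,1011.4,727.8,159151
786,966.2,735.1,160998
788,922,742.2,162694.4
790,880.1,749.6,164241.5
792,841.6,758,165640.6
794,807.9,767.9,166893
796,780,780,168000
798,766.9,797.8,168955.2
800,762,816,169692.2
802,753.7,829.4,170122.7
804,744.9,841.9,170158.1
806,735.9,853.3,169762
808,727.1,864,169173.3
810,718.6,873.9,168395.1
812,710.9,883.2,167379.8
814,704.1,891.9,166080
816,698.7,900.2,164448.4
818,694.9,908.2,162437.5
820,693,916,160000
822,692.3,923.3,157080
824,691.7,929.7,153706.7
826,691.3,935.5,149960
828,691,940.8,145920
830,690.8,945.8,141666.7
832,690.7,950.5,137280
834,690.6,955.1,132840
836,690.4,959.8,128426.7
838,690.3,964.7,124120
840,690,970,120000
842,689.3,975.3,116000
844,687.8,980.2,112000
846,685.7,984.8,108000
848,683.2,989.5,104000
850,680.4,994.3,1e+05
852,677.3,999.4,96000
854,674.2,1004.9,92000
856,671.2,1011.1,88000
858,668.4,1018.1,84000
860,666,1026,80000
862,663.4,1036.7,75920.6
864,660.9,1049.3,71841.3
866,660,1060,68000
868,660.7,1067.5,64373.2
870,662.1,1073.5,60801.7
872,664.2,1078.4,57320.7
874,667,1082.9,53965
876,670.6,1087.6,50769.7
878,674.9,1093.1,47769.7
880,680,1100,45000
882,686,1108.1,42479.3
884,693,1117,40177.1
886,700.7,1126.4,38055
888,709,1136.3,36074.3
890,717.7,1146.4,34196.4
892,726.6,1156.8,32382.9
894,735.7,1167.3,30595
896,744.7,1177.7,28794.3
898,753.6,1188,26942.1
900,762,1198,25000
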