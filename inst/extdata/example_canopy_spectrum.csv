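"wavelength_nm","reflectance"
397,0.0175217715311615
400.014851485149,0.0174952167137518
403.029702970297,0.0174754909403194
406.044554455446,0.0174598009395953
409.059405940594,0.0174465104729956
412.074257425743,0.0174346649688247
415.089108910891,0.0174237072656797
418.10396039604,0.0174133112095249
421.118811881188,0.0174032856450296
424.133663366337,0.0173935196106741
427.148514851485,0.0173839514522663
430.163366336634,0.0173745519194956
433.178217821782,0.0173653156999216
436.193069306931,0.0173562584248973
439.207920792079,0.0173474176905029
442.222772277228,0.0173388574987095
445.237623762376,0.0173306759398524
448.252475247525,0.0173230159452719
451.267326732673,0.0173160784710317
454.282178217822,0.0173101364474951
457.29702970297,0.0173055463137991
460.311881188119,0.0173027524125248
463.326732673267,0.0173022789955224
466.341584158416,0.0173047065765016
469.356435643564,0.0173106349971839
472.371287128713,0.017320644287074
475.386138613861,0.0173352729512299
478.40099009901,0.017355036657241
481.415841584158,0.0173805047162969
484.430693069307,0.0174124384874593
487.445544554455,0.0174519814772027
490.460396039604,0.0175008833083119
493.475247524752,0.0175617422076349
496.490099009901,0.0176382594258993
499.50495049505,0.0177355057291283
502.519801980198,0.0178601969464581
505.534653465347,0.018020958852077
508.549504950495,0.0182285331210494
511.564356435644,0.0184958430553507
514.579207920792,0.0188378135231153
517.594059405941,0.0192708425390016
520.608910891089,0.0198118705494936
523.623762376238,0.0204770949300683
526.638613861386,0.0212805140209812
529.653465346535,0.0222326089341
532.668316831683,0.0233395280169904
535.683168316832,0.024603051961387
538.69801980198,0.0260214455106063
541.712871287129,0.027591064084668
544.727722772277,0.0293083446963768
547.742574257426,0.0311717629161618
550.757425742574,0.0331833797081438
553.772277227723,0.0353497580920439
556.787128712871,0.037682211295792
559.80198019802,0.0401964848663479
562.816831683168,0.042912041087306
565.831683168317,0.0458511046177976
568.846534653465,0.0490375615172101
571.861386138614,0.0524956980088735
574.876237623762,0.0562486269347127
577.891089108911,0.0603160696587877
580.905940594059,0.0647109173048673
583.920792079208,0.0694336638130545
586.935643564356,0.0744633851088902
589.950495049505,0.0797435220769861
592.965346534653,0.0851606220836569
595.980198019802,0.0905151838840663
598.99504950495,0.0954873624847021
602.009900990099,0.0996070476918675
605.024752475248,0.102258414541161
608.039603960396,0.102752156001162
611.054455445545,0.100492526102444
614.069306930693,0.0952156929925524
617.084158415842,0.0871824263526261
620.09900990099,0.0771828227651032
623.113861386139,0.0663168943962984
626.128712871287,0.0556748380185779
629.143564356436,0.0460880229188334
632.158415841584,0.0380316605092565
635.173267326733,0.0316534578966284
638.188118811881,0.0268631231599833
641.20297029703,0.023431722004415
644.217821782178,0.0210755057856912
647.232673267327,0.0195155334364135
650.247524752475,0.0185126303939593
653.262376237624,0.0178812913241841
656.277227722772,0.0174887055307846
659.292079207921,0.0172457779474405
662.306930693069,0.0170958163632077
665.321782178218,0.0170043452642723
668.336633663366,0.0169514419775601
671.351485148515,0.0169266975906692
674.366336633663,0.0169263934999935
677.381188118812,0.0169524816944399
680.39603960396,0.0170132017396299
683.410891089109,0.0171255055049468
686.425742574257,0.017319804006153
689.440594059406,0.0176477892721331
692.455445544554,0.018194011098013
695.470297029703,0.0190912182932413
698.485148514852,0.0205380546239002
701.5,0.0228158952898747
704.514851485148,0.026300485573694
707.529702970297,0.0314647135074654
710.544554455446,0.0388714385985774
713.559405940594,0.049157407488251
716.574257425743,0.0630089344163791
719.589108910891,0.0811251028681293
722.60396039604,0.104156462845768
725.618811881188,0.132599804957847
728.633663366337,0.166628854890325
731.648514851485,0.205859165529898
734.663366336634,0.249100959745431
737.678217821782,0.294243889600071
740.693069306931,0.338468006438033
743.707920792079,0.378852291657153
746.722772277228,0.413153452049109
749.737623762376,0.440330560552316
752.752475247525,0.46055699498822
755.767326732673,0.474828197119825
758.782178217822,0.484467936426758
761.79702970297,0.490759613988583
764.811881188119,0.494761979375322
767.826732673267,0.497264780618957
770.841584158416,0.498818008147653
773.856435643564,0.49978610457109
776.871287128713,0.500401575454918
779.886138613861,0.500808315287686
782.90099009901,0.501093146768844
785.915841584158,0.501307325498119
788.930693069307,0.501480539902975
791.945544554455,0.501629703991722
794.960396039604,0.501764316340851
797.975247524752,0.501889640548204
800.990099009901,0.502008546777963
804.00495049505,0.502122550509049
807.019801980198,0.502232389124101
810.034653465347,0.502338333322115
813.049504950495,0.502440333358528
816.064356435644,0.502538095959676
819.079207920792,0.502631108434765
822.094059405941,0.50271863465349
825.108910891089,0.502799692910572
828.123762376238,0.502873020651377
831.138613861386,0.502937028435294
834.153465346535,0.502989744290161
837.168316831683,0.503028749167893
840.183168316832,0.503051104233184
843.19801980198,0.503053271043172
846.212871287129,0.503031026227331
849.227722772277,0.502979373013666
852.242574257426,0.502892452843627
855.257425742574,0.502763461347174
858.272277227723,0.502584574073095
861.287128712871,0.502346888531638
864.30198019802,0.502040390227092
867.316831683168,0.501653951330509
870.331683168317,0.501175371332858
873.346534653465,0.500591469267767
876.361386138614,0.499888236724792
879.376237623762,0.4990510597117
882.391089108911,0.498065015310009
885.405940594059,0.496915245894169
888.420792079208,0.495587409427337
891.435643564356,0.494068199100936
894.450495049505,0.492345919595416
897.465346534653,0.490411100915322
900.480198019802,0.488257124659121
903.49504950495,0.485880832408736
906.509900990099,0.483283082397627
909.524752475248,0.480469219417198
912.539603960396,0.477449424554984
915.554455445545,0.474238916043687
918.569306930693,0.470857980088405
921.584158415842,0.467331820481613
924.59900990099,0.463690227205739
927.613861386139,0.459967075907352
930.628712871287,0.456199680868774
933.643564356436,0.452428032770341
936.658415841584,0.44869395827454
939.673267326733,0.445040240814419
942.688118811881,0.441509740921046
945.70297029703,0.438144550380709
948.717821782178,0.434985208191478
951.732673267327,0.432069998591999
954.747524752475,0.429434343300265
957.762376237624,0.427110292375583
960.777227722772,0.425126111473699
963.792079207921,0.423505958152495
966.806930693069,0.42226963652737
969.821782178218,0.421432417996371
972.836633663366,0.421004915824605
975.851485148515,0.420993002857654
978.866336633663,0.421397764221931
981.881188118812,0.42221548023066
984.89603960396,0.423437638499708
987.910891089109,0.425050978136069
990.925742574257,0.427037572442643
993.940594059406,0.429374959536259
996.955445544554,0.432036332261123
999.970297029703,0.434990799479741
1002.98514851485,0.438203729971513
1006,0.441637187588635
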