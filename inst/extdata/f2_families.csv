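sample_id,population_id,ploidy,pcg_00011,pcg_00012,pcg_00024,pcg_00050,pcg_00058,pcg_00059,pcg_00106,pcg_1186,pcg_14142,pcg_00061,pcg_00062,pcg_7965
13-F1008,13_F1008,4X,GG,GG,AA,TC,GT,CG,CG,CT,GC,TG,GC,AA
F2:2012_13_F1_008_1,13_F1008,4X,GG,GG,AA,TC,GT,CG,GG,TT,GG,GG,GG,AA
F2:2012_13_F1_008_2,13_F1008,4X,GG,GG,AA,TT,GT,CG,GG,TT,GG,TG,GC,AA
F2:2012_13_F1_008_3,13_F1008,4X,GG,GG,AA,TC,GT,CG,CG,CT,GC,TG,GC,AA
F2:2012_13_F1_008_4,13_F1008,4X,GG,GG,AA,TC,GG,CC,CG,CT,GC,TG,GC,AA
F2:2012_13_F1_008_5,13_F1008,4X,GA,GA,TA,TT,TT,GG,CG,CC,GG,TT,CC,AG
F2:2012_13_F1_008_6,13_F1008,4X,GA,GA,TA,TC,GT,CG,CC,CC,GC,TG,CC,AG
F2:2012_13_F1_008_7,13_F1008,4X,GG,GG,AA,TC,TT,GG,CG,CC,GC,TT,CC,AA
F2:2012_13_F1_008_8,13_F1008,4X,GG,GG,AA,CC,TT,GG,CG,TT,GC,GG,GG,AA
F2:2012_13_F1_008_9,13_F1008,4X,GG,GG,AA,TC,GG,CC,GG,CT,GC,TG,GC,AA
13-F1011,13_F1011,4X,GG,GG,AA,TC,GT,CG,CG,CT,GC,GG,GG,AG
F2:2012_13_F1_011_1,13_F1011,4X,GG,GG,AA,TC,TT,GG,GG,CT,GC,GG,GG,AG
F2:2012_13_F1_011_3,13_F1011,4X,GG,GG,AA,TT,GT,CG,CG,CT,GC,GG,GG,AG
F2:2012_13_F1_011_4,13_F1011,4X,GG,GG,AA,CC,GT,CG,GG,CT,GC,GG,GG,AG
F2:2012_13_F1_011_5,13_F1011,4X,GG,GG,AA,TT,GT,CG,CG,CT,GC,GG,GG,GG
F2:2012_13_F1_011_6,13_F1011,4X,GG,GG,AA,CC,GT,CG,CG,CC,GC,GG,GG,AA
F2:2012_13_F1_011_7,13_F1011,4X,GG,GG,AA,CC,GG,CC,GG,CC,GC,GG,GG,AG
F2:2012_13_F1_011_8,13_F1011,4X,GG,GG,AA,TC,GT,CG,CG,CT,GC,GG,GG,AA
F2:2012_13_F1_011_9,13_F1011,4X,GG,GG,AA,TC,GT,CG,CG,CT,GC,GG,GG,AG
F2:2012_13_F1_011_10,13_F1011,4X,GG,GG,AA,CC,TT,GG,CG,CC,GC,GG,GG,AG
F2:2012_13_F1_011_2,13_F1011,4X,GG,GG,AA,TC,GT,CG,CG,CT,GC,GG,GG,AA
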