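sample_id,population_id,ploidy,pcg_00011,pcg_00012,pcg_00024,pcg_00050,pcg_00058,pcg_00059,pcg_00106,pcg_1186,pcg_14142,pcg_00061,pcg_00062,pcg_7965
PC17_109,parent,4X,GA,GA,TA,TT,GG,CC,CC,CC,GG,TG,GC,AG
PC20_102,parent,4X,GG,GG,AA,CC,TT,GG,GG,TT,CC,TG,GC,AG
13_F1001,F1_13,4X,GG,GG,AA,CC,TT,GG,GG,TT,CC,TT,CC,AG
13_F1002,F1_13,4X,GA,GA,TA,TC,GT,CG,CG,CT,GC,GG,GG,GG
13_F1003,F1_13,4X,GA,GA,TA,TC,GT,CG,CG,CT,GC,GG,GG,AG
13_F1004,F1_13,4X,GA,GA,TA,TC,GT,CG,CG,CT,GC,TG,GC,AA
13_F1005,F1_13,4X,GA,GA,TA,TC,GT,CG,CG,CT,GC,TT,CC,AG
13_F1006,F1_13,4X,GA,GA,TA,TC,GT,CG,CG,CT,GC,TG,GC,AG
13_F1007,F1_13,4X,GG,GG,AA,CC,TT,GG,GG,TT,CC,GG,GG,AG
13_F1008,F1_13,4X,GG,GG,AA,TC,GT,CG,CG,CT,GC,TG,GC,AA
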