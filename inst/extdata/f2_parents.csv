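sample_id,population_id,ploidy,pcg_00011,pcg_00012,pcg_00024,pcg_00050,pcg_00058,pcg_00059,pcg_00106,pcg_1186,pcg_14142,pcg_00061,pcg_00062,pcg_7965
13-F1008,F1_parent,4X,GG,GG,AA,TC,GT,CG,CG,CT,GC,TG,GC,AA
13-F1011,F1_parent,4X,GG,GG,AA,TC,GT,CG,CG,CT,GC,GG,GG,AG
14-F1008,F1_parent,4X,GA,GA,TA,TC,GT,CG,CG,CT,GC,TT,CC,AG
14-F1014,F1_parent,4X,GG,GG,AA,TC,GT,CG,CG,CT,GC,TG,GC,AG
14-F1015,F1_parent,4X,GG,GG,AA,TC,GT,CG,CG,CT,GC,TT,CC,AG
14-F1042,F1_parent,4X,GG,GG,AA,TC,GT,CG,CG,CT,GC,GG,GG,AG
14-F1067,F1_parent,4X,GG,GG,AA,TC,GT,CG,CG,CT,GC,TG,GC,GG
14-F1071,F1_parent,4X,GA,GA,TA,TC,GT,CG,CG,CT,GC,TG,GC,AA
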