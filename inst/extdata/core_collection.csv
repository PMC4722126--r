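sample_id,population_id,ploidy,pcg_00006,pcg_00008,pcg_00009,pcg_00010,pcg_00011,pcg_00012,pcg_00013,pcg_00014,pcg_00015,pcg_00016,pcg_00017,pcg_00018,pcg_00021,pcg_00022,pcg_00023,pcg_00024,pcg_00025,pcg_00026,pcg_00027,pcg_00028,pcg_00029,pcg_00032,pcg_00034,pcg_00037,pcg_00042,pcg_00049,pcg_00050,pcg_00058,pcg_00059,pcg_00060,pcg_00061,pcg_00062,pcg_00065,pcg_00066,pcg_00078,pcg_00081,pcg_00083,pcg_00084,pcg_00085,pcg_00088,pcg_00092,pcg_00093,pcg_00098,pcg_00101,pcg_00102,pcg_00103,pcg_00104,pcg_00106,pcg_00109,pcg_00110,pcg_00111,pcg_00112,pcg_7965,pcg_14142,pcg_1186,pcg_77221,pcg_13880,pcg_2412,pcg_37652
PC19_103_1,PC19_103,4X,-,AA,AA,TT,GA,GA,CT,GT,AG,GA,AG,TC,AG,AA,CG,AA,GG,GT,GA,AC,GA,CA,GG,CC,GG,AG,TT,GG,CC,TT,GG,GG,GG,GG,AC,TT,CT,TA,-,AA,CC,GG,CC,GG,AG,TC,CC,CG,GG,GG,CC,AA,AG,GC,CT,GG,GG,GG,CC
PC19_103_2,PC19_103,4X,-,AA,AA,TT,GA,GA,CT,GT,AG,GA,AG,TC,AG,AA,CG,AA,GG,GT,GA,AC,GA,CA,GG,CC,GG,AG,TT,GG,CC,TT,GG,GG,GG,-,AC,TT,CT,TA,-,AA,CC,GG,CC,GG,AG,TC,CC,CG,GG,GG,CC,AA,AG,GC,CT,GG,GG,GG,CC
PC20_104_1,PC20_104,8X,GA,-,-,-,-,-,CT,GT,AG,GA,AG,TC,AG,GA,CG,TA,AG,GT,GA,AC,GA,CA,GA,CT,GA,GG,CC,GT,GG,AT,TG,GC,-,GC,AC,AT,TT,AA,AC,GA,CC,AG,-,GG,AG,CC,GC,-,GA,GT,CC,AA,GG,GC,CT,TT,GG,GG,CC
PC20_104_2,PC20_104,8X,GA,-,-,-,-,-,CT,GT,AG,GA,AG,TC,AG,GA,CG,TA,AG,GT,GA,AC,GA,CA,GA,CT,GA,GG,CC,GT,GG,AT,TG,GC,-,GC,AC,AT,TT,AA,AC,GA,CC,AG,-,GG,AG,CC,GC,-,GA,GT,CC,AA,-,GC,GT,TT,GG,GG,CC
PC34_101_1,PC34_101,4X,GA,CA,-,TT,GA,GA,CC,GG,AA,AA,AA,TT,AA,AA,CC,-,GG,GG,GG,AA,GG,CC,GG,CC,GG,AA,TT,GG,CG,TT,TG,GC,AG,GG,AC,TT,CT,TA,AA,-,CT,GG,CC,GG,AA,TC,CC,CC,GG,GG,GC,AA,GG,GG,CT,GG,GG,GG,CC
PC34_101_2,PC34_101,4X,GA,AA,-,CT,-,GA,CT,GT,AG,-,AG,TC,AG,-,CG,TA,-,GT,-,AC,GA,CA,-,-,-,-,CC,GT,-,-,TG,-,AG,GC,-,TT,CT,TA,CC,-,CT,GG,AC,AG,AG,CC,CC,CG,GG,GG,-,AA,-,-,TT,GG,GG,GG,CC
PC38_101_1,PC38_101,8X,GA,CA,GA,-,AA,AA,TT,GT,GG,-,GG,CC,GG,GA,GG,TA,AG,TT,AA,CC,AA,AA,GA,CT,GA,GG,CC,GT,GG,-,GG,GG,GG,GC,AC,TT,CT,TT,AC,GA,CT,AG,CC,AG,AG,TC,GC,CG,GA,-,CC,AA,GG,GC,TT,GG,GG,GG,CC
PC38_101_2,PC38_101,8X,GA,-,-,TT,GA,GA,-,GT,AG,-,AG,TC,AG,AA,CG,TA,GG,GT,GA,AC,GA,-,GG,CC,GG,AA,TT,GG,CC,AT,GG,GG,GG,GC,CC,TT,CC,TT,CC,GG,TT,GG,AA,-,AG,CC,CC,CC,GG,GG,GC,AA,AG,GG,CT,GG,GG,GG,CC
Red_River_1,Red_River,8X,AA,CA,GA,CT,GA,GA,CT,GT,AG,GA,AG,TC,AG,GA,CG,TA,AG,GT,GA,AC,GA,CA,GA,CT,GA,AG,CC,GT,GG,TT,TG,GC,AG,GC,AC,AT,CT,TA,CC,GA,CT,AG,AC,AG,GG,-,GC,-,GG,GT,GC,AA,GG,GC,CT,GG,GG,GG,CC
Red_River_2,Red_River,8X,AA,AA,AA,CT,GA,GA,CT,GG,AG,AA,AG,TC,AG,AA,CG,AA,GG,GT,-,AC,GA,CA,GA,CT,GA,AG,CC,GT,CG,AT,TG,GC,-,GC,CC,AT,CT,TA,CC,GA,CT,AG,AC,GG,AG,CC,CC,-,GG,GT,GC,AA,AG,-,TT,GG,GG,GG,CC
PC17_109,PC17_109,4X,GA,CA,-,TT,GA,GA,CC,GG,AA,AA,AA,TT,AA,AA,CC,TA,GG,GG,GG,AA,GG,CC,GG,CC,GG,AA,TT,GG,CC,TT,TG,GC,AG,GG,CC,TT,CC,TT,AC,GG,TT,GG,AC,AG,AG,TC,CC,CC,GG,GG,GC,AA,AG,GG,CC,GG,GG,GG,CC
PC20_102,PC20_102,4X,GA,AA,AA,TT,GG,GG,CC,GG,AA,AA,AA,TT,AA,AA,CC,AA,GG,GG,GG,AA,GG,CC,GG,CC,GG,AG,CC,TT,GG,TT,TG,GC,GG,GC,CC,AT,CT,TA,CC,GA,CT,AG,CC,GG,AA,CC,CC,GG,GA,GT,CC,AA,AG,CC,TT,GG,GG,GG,CC
S_alterniflora_East,S_alterniflora_East,unknown,AA,CC,AA,TT,AA,AA,CC,-,-,GG,GG,CC,AA,AA,CC,AA,GG,GG,GG,AA,GG,CC,GG,CC,-,GG,CC,GG,GG,AA,-,CC,GG,GC,CC,TT,TT,AA,CC,GG,TT,GG,AA,GG,GG,CC,-,CG,GG,TT,-,AA,GG,CC,-,-,-,-,-
S_bakeri,S_bakeri,unknown,AA,CC,AA,TT,AA,AA,CC,-,-,GG,GG,CC,AA,AA,CC,TA,GG,GG,GG,AA,GG,CC,GG,CC,-,GG,CC,GG,GG,AA,TT,CC,GG,GC,CC,TT,TT,AA,CC,GG,CC,AG,AA,GG,GG,TT,CC,CG,GG,TT,CC,AA,GG,CC,-,-,-,-,-
S_patens_Sharp,S_patens_Sharp,unknown,AA,CC,AA,TT,AA,AA,CC,-,-,GG,GG,CC,AA,AA,CC,AA,GG,GG,GG,AA,GG,CC,GG,CC,-,GG,CC,GG,GG,AA,TT,CC,GG,GC,CC,TT,TT,AA,CC,GG,CC,AG,AA,GG,GG,TC,CC,GG,GG,TT,CC,AA,GG,CC,-,-,-,-,-
S_patens_Flageo,S_patens_Flageo,unknown,AA,CC,AA,TT,AA,AA,CC,-,-,GG,GG,CC,AA,AA,CC,AA,GG,GG,GG,AA,GG,CC,GG,CC,-,GG,CC,GG,GG,AA,TT,CC,GG,GC,CC,TT,TT,AA,CC,GG,CC,AG,AA,GG,GG,CC,CC,GG,GG,TT,CC,AA,GG,CC,-,-,-,-,-
S_patens,S_patens,unknown,AA,CC,AA,TT,AA,AA,CC,-,-,GG,GG,CC,AA,AA,CC,AA,GG,GG,GG,AA,GG,CC,GG,CC,-,GG,CC,GG,GG,AA,TT,CC,GG,GC,CC,TT,TT,AA,CC,GG,CC,GG,AA,GG,GG,CC,CC,GG,GG,TT,CC,AA,GG,CC,-,-,-,-,-
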