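sample_id,population_id,ploidy,pcg_00001,pcg_00032,pcg_00002,pcg_00033,pcg_00003,pcg_00034,pcg_00004,pcg_00035,pcg_00005,pcg_00036,pcg_00006,pcg_00037,pcg_00007,pcg_00038,pcg_00008,pcg_00039,pcg_00009,pcg_00040,pcg_00010,pcg_00041,pcg_00011,pcg_00042,pcg_00012,pcg_00043,pcg_00013,pcg_00044,pcg_00014,pcg_00045,pcg_00015,pcg_00046,pcg_00016,pcg_00047,pcg_00017,pcg_00048,pcg_00018,pcg_00049,pcg_00019,pcg_00050,pcg_00020,pcg_00051,pcg_00021,pcg_00052,pcg_00022,pcg_00053,pcg_00023,pcg_00054,pcg_00024,pcg_00055,pcg_00025,pcg_00056,pcg_00026,pcg_00057,pcg_00027,pcg_00058,pcg_00028,pcg_00059,pcg_00029,pcg_00060,pcg_00030,pcg_00061,pcg_00031,pcg_00062,pcg_00063,pcg_00093,pcg_00064,pcg_00094,pcg_00065,pcg_00095,pcg_00066,pcg_00096,pcg_00067,pcg_00097,pcg_00068,pcg_00098,pcg_00069,pcg_00099,pcg_00070,pcg_00100,pcg_00071,pcg_00101,pcg_00072,pcg_00102,pcg_00073,pcg_00103,pcg_00074,pcg_00104,pcg_00075,pcg_00105,pcg_00076,pcg_00106,pcg_00077,pcg_00107,pcg_00078,pcg_00108,pcg_00079,pcg_00109,pcg_00080,pcg_00110,pcg_00081,pcg_00111,pcg_00082,pcg_00112,pcg_00083,pcg_1186,pcg_00084,pcg_13880,pcg_00085,pcg_14142,pcg_00086,pcg_2412,pcg_00087,pcg_37652,pcg_00088,pcg_38909,pcg_00089,pcg_77221,pcg_00090,pcg_7965,pcg_00091,pcg_80876,pcg_00092
SYN_1,synthetic,4X,-,AA,-,-,AA,AA,GG,-,AA,-,AA,TT,AA,-,AA,-,AA,-,TT,-,AA,AA,AA,-,TT,-,TT,TT,GG,-,AA,-,GG,CC,CC,GG,AA,CC,GG,TT,GG,AA,AA,TT,GG,GG,AA,CC,GG,-,TT,CC,AA,TT,CC,GG,AA,TT,GG,GG,TT,CC,CC,GG,CC,CC,GG,-,CC,-,CC,-,-,CC,AA,AA,TT,-,AA,GG,-,GG,CC,CC,-,CC,GG,TT,CC,GG,-,CC,CC,GG,TT,AA,TT,TT,TT,CC,-,AA,TT,TT,AA,GG,CC,CC,-,GG,-,CC,AA,-,TT,GG,AA,GG,CC,GG,TT
SYN_2,synthetic,4X,-,AC,-,-,AA,AG,GG,-,AA,-,AG,CT,AA,-,AC,-,AG,-,CT,-,AG,AG,AG,-,CT,-,GT,TT,AG,-,AG,-,AG,CC,CT,AG,AA,CT,GG,CT,AG,AG,AG,CT,CG,AG,AT,CG,AG,-,GT,CG,AG,GT,AC,CG,AG,AT,AG,GT,CT,CG,CT,AG,CT,CT,AG,-,CG,-,CT,-,-,AC,AT,AT,GT,-,AC,AG,-,AG,CT,CT,-,CG,CG,CT,CG,CG,-,AC,AC,AG,CT,AG,GT,GT,AT,CG,-,AA,CT,CT,AT,GG,AC,CG,-,GG,-,AC,AG,-,CT,GT,AG,AG,CT,AG,CT
SYN_3,synthetic,4X,-,AC,-,-,AA,AG,GG,-,AA,-,AG,CT,AA,-,AC,-,AG,-,CT,-,AG,AG,AG,-,CT,-,GT,TT,AG,-,AG,-,AG,CC,CT,AG,AA,CT,GG,CT,AG,AG,AG,CT,CG,AG,AT,CG,AG,-,GT,CG,AG,GT,AC,CG,AG,AT,AG,GT,CT,CG,CT,AG,CT,CT,AG,-,CG,-,CT,-,-,AC,AT,AT,GT,-,AC,AG,-,AG,CT,CT,-,CG,CG,CT,CG,CG,-,AC,AC,AG,CT,AG,GT,GT,AT,CG,-,AA,CT,CT,AT,GG,AC,CG,-,GG,-,AC,AG,-,CT,GT,AG,AG,CT,AG,CT
SYN_4,synthetic,4X,-,CC,-,-,AA,GG,GG,-,AA,-,GG,CC,AA,-,CC,-,GG,-,CC,-,GG,GG,GG,-,CC,-,GG,TT,AA,-,GG,-,AA,CC,TT,AA,AA,TT,GG,CC,AA,GG,GG,CC,CC,AA,TT,GG,AA,-,GG,GG,GG,GG,AA,CC,GG,AA,AA,TT,CC,GG,TT,AA,TT,TT,AA,-,GG,-,TT,-,-,AA,TT,TT,GG,-,CC,AA,-,AA,TT,TT,-,GG,CC,CC,GG,CC,-,AA,AA,AA,CC,GG,GG,GG,AA,GG,-,AA,CC,CC,TT,GG,AA,GG,-,GG,-,AA,GG,-,CC,TT,GG,AA,TT,AA,CC
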