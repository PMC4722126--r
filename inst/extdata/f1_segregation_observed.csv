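primer_id,test,allele_x,allele_y,obs_x_hom,obs_y_hom,obs_het
pcg_00011,1:1,A,G,0,44,35
pcg_00012,1:1,A,G,0,43,35
pcg_00024,1:1,A,T,43,0,35
pcg_00050,1:1,C,T,0,0,77
pcg_00058,1:1,T,G,0,0,77
pcg_00059,1:1,G,C,0,0,78
pcg_00106,1:1,G,C,0,0,75
pcg_1186,1:1,T,C,0,0,78
pcg_14142,1:1,C,G,0,0,79
pcg_00061,1:2:1,G,T,27,15,37
pcg_00062,1:2:1,C,G,15,27,37
pcg_7965,1:2:1,G,A,17,20,42
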