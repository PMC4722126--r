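snp_id,context
pcg_00001,GTCCTTGAGCTCGGC[G/A]TCCACGTCCAAGCG
pcg_00032,GCCAGTATTGGCAAG[A/C]ATGCAACAATTACT
pcg_00002,CGCCAGGTACACCGG[C/G]GCCGCCTGGTTAGT
pcg_00033,AAAGACTACCCTTCC[A/C]TATCGAATAGAGAA
pcg_00003,GTCGGCCCCGGCCTC[A/G]AACCACGGGACGCC
pcg_00034,ACAGCTCCGGATGAA[A/G]TGGTACTTGATCCG
pcg_00004,ACCCGAAGGAGAAGG[G/T]CGCGATGGCGCCCG
pcg_00035,TCTTTCGACCAAGTA[A/G]CTCACCCAGTAGGC
pcg_00005,AAGAACAAATTTATA[A/G]GTTAAATACATGCA
pcg_00036,GCTCGTGTCGATGTC[G/A]CCGGCGAGGTCGCT
pcg_00006,GCCAAAGGACAGATC[A/G]TGAATAACATGACT
pcg_00037,CGAGGTGTGATGCAC[T/C]AGAACGCCGCTCGT
pcg_00007,CGGAACTGAGGAACA[A/G]TAGCATACATGCTT
pcg_00038,GCTCACATACCCGAC[A/G]GCGAACGCCAAGTC
pcg_00008,GTTCGACCGCGCGGC[A/C]ATCGCCGAGCTCGA
pcg_00039,TGGGCAGGGTTGCAG[T/C]CACCCATGCCTCCC
pcg_00009,GAGAAGAAGAGAGTG[A/G]TTGCATCATTGGAC
pcg_00040,CGCTTCTTCCGTGCC[A/G]GTGATGACGAGGTC
pcg_00010,GGTGCGGCTTGACAA[T/C]GTCACAATACAAGT
pcg_00041,GTGTCCCCGGCCTCG[C/T]CGGTACACCGCCGC
pcg_00011,CTGTTTGTTAAGTGC[A/G]CTGAATTTGAGATT
pcg_00042,GCGGTGCTTGCCGCA[A/G]CCCGTACAAGGCCT
pcg_00012,GCATTCATGTTCCCA[A/G]TACATCCTGGCAAA
pcg_00043,CTTCTTGAGCTTGAA[T/C]ACCCACTTCAGGGT
pcg_00013,ACAATCATTGTTTTT[T/C]GTAATTGGGGAACT
pcg_00044,CGGGCGGTGGCCGGC[T/C]GGCAAGTCGACGAG
pcg_00014,CCAAATGGCAAAAAT[T/G]TACTCAGATTTCCA
pcg_00045,AAGTCAGTTGTTGTC[T/A]GCAACCCTCATCGT
pcg_00015,ACTTGATTTAGAGTC[G/A]GCAGACATCATTTT
pcg_00046,TCTGTTTGATTACCA[C/T]GGTAAGCTCACTCA
pcg_00016,AGCGCTTCACGCGAT[A/G]GAGTTCTCCGAAAT
pcg_00047,TTACCAAATACCCAG[A/G]TGCAGAGTTCAAGC
pcg_00017,TAGCTTTAGGTGTTG[G/A]GTTTCGCATCAGTA
pcg_00048,AAGCAACAACTTACT[C/T]GAGCAAAGTGCAAG
pcg_00018,AGAACCAACTCTTTA[C/T]ATCAGACTGCGTAT
pcg_00049,TTACTTTCATATAAC[G/A]GGATGAAGCATGCA
pcg_00019,AACAAAGACAACATG[A/G]CTCACGAGAAATTG
pcg_00050,CAGGGACATTCGTTT[C/T]GTCCTCCAAAAATA
pcg_00020,TTTGGATGTTGAACT[G/A]TCTCAGATGTCCTT
pcg_00051,CCCTTGAATGGCTTC[T/C]TTTTCTTTTGTGCA
pcg_00021,TTTGGATGTTGAACT[G/A]TCTCAGATGTCCTT
pcg_00052,CACCAACCACTTGTC[A/G]TGGTGACGCTTCGT
pcg_00022,ATGAATTTTGGCACG[A/G]ACTTTTTGTTTGAA
pcg_00053,CGAGGTTGATGTTTA[T/C]GCTCGTCGATGACG
pcg_00023,GCATCCACAAGAATG[G/C]CCATGAACAATTAA
pcg_00054,AAAGTATTTGTAGGA[G/A]ACCCCTGAGGGTTC
pcg_00024,GATCGAGAAAAAAAA[A/T]TTGGATGAAGATTC
pcg_00055,CTCGCGTGGCCTTCT[C/G]TGTCATAAACCATG
pcg_00025,TTTGAGGAGGACGGT[G/A]ATGATAGCAAATCT
pcg_00056,GGAACGTATCCTGTG[T/C]ATAAGGGCTCTCCG
pcg_00026,GTGAGGGATAGATTG[T/G]CAAGCAATGCAAGT
pcg_00057,AACTTGGTATCAGAC[C/G]GCCAAGGTTAAACC
pcg_00027,CCATCTAAGGTCAGG[A/G]TTCTAAGTTCATTC
pcg_00058,GGCACGGTAAACCTT[T/G]GCAAAGGTCCCTTG
pcg_00028,ACATTCTTCCGATCT[C/A]GGGTTTTTAACCCA
pcg_00059,TCAACCGTCTCCCCC[G/C]AGATGATTGTCTAA
pcg_00029,GGACCATTTGTTGTC[A/G]TCAAGGTTTCCCAG
pcg_00060,CACCCCACAAGACCA[T/A]ATGTCGGCTTTTGC
pcg_00030,GAGAGCATTGATGTC[G/A]CTGGCTCTTGGAAA
pcg_00061,AAATCTTTTTTTCCA[G/T]TATCTTTTTTCTTA
pcg_00031,AGTTAGACCTGAGAT[T/C]GAACATTCTGAAAA
pcg_00062,GTAATTGTTTGCAGA[C/G]AACTTTTCATTTGT
pcg_00063,GGAAGATATGCAACA[C/T]TTTGGGGAGGAAGC
pcg_00093,TACTGGGAAGAAACC[G/A]TTCCACTTGTCCTG
pcg_00064,GGGGATGTCACCCTT[C/T]CCCGGCGCGGTGAT
pcg_00094,GCTCTCCGCACACGC[C/T]GCCACCGCTACATC
pcg_00065,CAGCGGCAGCGACGC[G/A]GCGCTCCTGAGCCC
pcg_00095,TGGTGAAAAGGTCCT[G/C]ATCCAGTTTGAGGA
pcg_00066,CGGCTTCGACCCGCT[C/G]GGCCTGGCGGAGGA
pcg_00096,CAGGGACCGGAACCG[G/A]TTCCACCGGTTCAG
pcg_00067,GAGGATGTTGTCGAG[C/T]TTGACGTCGCGGTG
pcg_00097,TTTTGTTACAAAATA[C/T]GAGCAAGCTCTGTT
pcg_00068,CAATCCTGGAAAGGA[C/T]CCACTAATGTTTGT
pcg_00098,GTACAATGTCTGGGC[C/A]AGTACTCCTAATGG
pcg_00069,TGAAGTAACTACTAA[A/T]ATAGTACTGTTGTA
pcg_00099,AAAAAAAAGATGATG[A/T]CAGGTTACAAATTG
pcg_00070,AGGCTCTCACGATCA[T/G]TCCGAGTCGCTGTC
pcg_00100,GACTCTCTACGGCTC[C/A]TCCAGGCTCACCGC
pcg_00071,GGCAAGGCTTTTACA[A/C]AAGAAGTTGTCGAG
pcg_00101,AGTACATGCAGGAGG[G/A]GCATTCTCTTCCTT
pcg_00072,GGAGTACAATGGAAA[A/G]CTTCATGTGCCTGG
pcg_00102,CCATTTGAATCTCAA[G/A]GCACTGACGTGAAC
pcg_00073,TTTCCCTGGATTTGG[C/T]CTGGGTCTTGTTAT
pcg_00103,GCTAGCTTTTGCGCC[C/T]CTATACATCTTTTC
pcg_00074,CGAGCATATAATATG[G/A]CCCTAAAATGATGG
pcg_00104,CGTCCTCGTCGTCTT[C/G]TTCCTCTGGCTGCT
pcg_00075,CGGCCGCGAGGACTC[G/C]CCGCTCGACATCAT
pcg_00105,GCTTGTGCTCATGGA[T/C]GTGGTTCACAGCCA
pcg_00076,CATCCCCACCTACGT[C/G]GTCGGAGTCAATGC
pcg_00106,ATTGGTGCTGTTGCT[G/C]GACGTGAAGCTGAC
pcg_00077,CTCCTGCACCACCAA[C/T]TGCCTCGCGCCCTT
pcg_00107,AGATGACGGAGTCGG[C/A]GACGACGTGGGAGC
pcg_00078,ATGGAGGGACACAGC[C/A]GGCAAAGTGGATGT
pcg_00108,CTCTTTGCGCATGTG[G/A]CTCTTTTCCAGGGC
pcg_00079,AGATTCTGATATTGA[T/C]TTGGATGACTATTC
pcg_00109,ACTCAGACCATTTTG[A/G]ACCACCTCAGATGT
pcg_00080,TGCGTATATTCTCCG[T/G]GGTGAGACCAAAAT
pcg_00110,TATGTTATCTCAATG[T/G]GATCTACACCTGCA
pcg_00081,GCTCGCCCTCGCAAC[T/A]ATCGGATCTTGCGC
pcg_00111,GCCGACGGGATGCGG[C/G]CGATTCACATTTGC
pcg_00082,CTGGCTGTAGGAATG[G/A]CCTTTTCACCTGAA
pcg_00112,TGACCACATGCCATG[A/G]GTATCAAGCCTATT
pcg_00083,TGAAGTTATGTATGA[T/C]CTGAGAGCTAGTGG
pcg_1186,GACCTCGCAGAACAC[T/C]GCAGACATGACCTC
pcg_00084,AAGTTCGGGATCAGC[A/T]CCGTGTATTTGGGA
pcg_13880,TCAAGTACCTCACCG[G/A]CGAGGCCAAGGCTT
pcg_00085,CTTCTGAAGTCGGAA[C/A]TGCCATCAAACTGG
pcg_14142,CACGCAGTTGGGGGC[C/G]AGGATGAGGACGAC
pcg_00086,AGGAGTATCCACCTG[G/T]AATAACACTTGTAC
pcg_2412,CACATTGCGATTAGC[G/A]TATCGATCATGAAA
pcg_00087,CAACACAATGAATCG[T/G]ATTGGAAAAGGAAG
pcg_37652,ACTTGAAGAGAGACG[C/A]ATCTGAAGGCAGAT
pcg_00088,TTTACAAATGCATAA[A/G]ATCTATGTTGGTAA
pcg_38909,CACGCAGTTGGGGGC[C/G]AGGATGAGGACGAC
pcg_00089,CGTACCTGCAGTTCA[T/C]GTTCGCCTACATCT
pcg_77221,GAGCTCGCCAGGCAC[G/T]CTGGCTTCTGTGGC
pcg_00090,GAGGGGTAGTAAGAA[A/G]ACAAAGGAGACGTG
pcg_7965,TGACCAGCCGCAGCA[G/A]CCGCTCGTGGTAGT
pcg_00091,GGTACATAGTTTGAT[C/T]CACCTCCCTTCCTC
pcg_80876,TGGCGTCGTAGGTGC[G/A]CCACGGAGGACGCG
pcg_00092,ATGGGAAGACAGGTT[T/C]GCAGCTTCATTATT
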