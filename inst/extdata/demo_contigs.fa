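>contig_1
GTCCTTGAGCTCGGCGTCCACGTCCAAGCGCTGTGAATATGGATGACCCGGGGGGATATGGCCTAGGTCCGACCGACATCCCGAGAAAGCTAATTTGCAAATACCCGCGTCTGAGACACT
>contig_2
CCTTATTATCAGCCTACGCTAACAGCCCAAGATACACGTTTGCGAATGCAGGCGGGCCTGATTGCTGGAACCCCTCAGTTAACACGGACGCGCAAAGGATTAAGCTTAATTATCCATTGGGATGTGCTTGGTACTTCCTGAGAAGGGGTATAACAGAGTGGTGCCACGCCGCACGACTGGATGAAAGTTCGAGACGGATCAGTGATGATTCAGCTACAATCGCGACGTATAATGCCAGCTCTAAAGGTCCGGTTGAACAAATCCGGGCAGTTTGCCGGTTATTAACTTTTGATTCATTGATCGGGCCAGGCGCATCTCTGACACACTCCGCGTGGGCCCCGGGGCCGCCCGTATTGTATCCTTATGAACCCATTCACGCCCGCAGTGCACGACTGTCTGC
>contig_3
CGGCGGATGCTTCGTAATCCCCCATTCCGCAGATCTGGAAGATAGTTCATTAAGAGCGCTGCCTTTGCAGACCTTATGAACCGTACACGCTGAGACCCACAGACGCTAAACAATGGCCCCGGCTTGTGAGGTGCACCTTGGATTAAGGATGCGGATATAAGGTGTGGTTCTTTCGCTGTAATATTACTAATCCTCCGCGT
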