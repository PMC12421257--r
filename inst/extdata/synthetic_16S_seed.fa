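>synthetic_16S_seed synthetic seed marker, 1544 bp, generated (not a natural sequence)
GACGGAATCGGGTCTCGGTGCCCTCGAATGCATTCGGGCGTTGTCGCACTGGACCTTTCCGTTCCTAAAA
AGTTCTCAAGCTACTGGCGTATAGGCGGCGTCTGGGAGCTTTCACGGAGCGTCTCGGATATGCTCCACAC
TCCCGCTTCGGGGGCGTGCTATGATGACGAGCGTCCGTTGTCCCGACGTTTACGAGATTCGCTTTGACTA
GAGGTACAGATGACACATAATGGTTCAATTCAAATCGCGTGACAGGTAGGCCCCGGCGGAACCACTGTCG
GGCTAACCCGGCTCTGCTTCGGCTTAGCGATCCCGGCCTTATTTAACTGGCGGTGTGTAACCTACGGGAG
GCTGCAGCACAAATTCCTTGTTCTCTAGGAGCTATCTACCCAGCAGCGCGCGAATGACTAAGTGAGGTCG
CGCGCCACGCTTAACGCGGGGCCGTTCGGCTACGACGGCGGGCTGGAACCGCCTGCGCGACCAGAATTTT
AATCTCCGAAGACACGTCGGCAGAAATTTCCTCGAAGAGTACATGGCCTCTGTAGCAGGGTGCTGGACTA
TGCTATGCATGGGGAACAGTCGAACTGACCTTACGGAGCTGTGGCACAGATTGGTGTACTCTCATATGAA
GGAGTTCTGCTCTGAATAGGAAACACCTCCGTGAACTCCTGCAGGGGTAGGGTACACGATCGAACGAAAA
CCTGTGGTAAACTCCGGCACAACTCACGCGCAAGTCTCAGCCCTCGCAAAGTCAACAAAGATAGTTCGCC
CCCAGCTGGGAACAGGATTAGATACCCGGGTAGTCTGCGCTCATCAGCCCCCCTCGGGTTGCGACAATTT
GCTCGATAACCGACGCACTTCCCTGGCCGGGCTTCCCAACAAGGGCCGGGTCTGGTCTACAGAGACTTTG
GCAATCAAAACCTGTTATTTGAAGGAGAAGCTACCTAGGTGGTATTCGTGTCACGAGCGTATCTACTGTA
TGAGAAGTTTGGCGTCGAACCTCAAGGCTACGTCTTCCCGAGGACGCGCACTCGACGCCCCCCGACGACC
TCGCACACTCAGGCCGCAAAAAGCGGGCTGAGTCGTAGCCGTTTGGGTACACGGACTGGCTCCGACATTA
AAGCCGCGTTTCAGTGGCAGTCTCGGCGGTGATACCACACGGAATTCAATGGAAGGTGGGGATGACGTGT
AGCCGTCCTGGAGCAGCCGGCTAGCTAGTACGCCAATCAAAGTCATTTAGCTGACTTTTCAGCGACCCCT
CGTCATGGTCAGGGAGGCGGAACCGGCGCGGGAAGAAGTGCCAAGCCAAATTTGCGAGTGACGTACTCAT
CTTGTAGAGCGTCTTGAGTATTGCACACGTCTGCCGAAAGATGAGCCTGATGAGGCAGGCCAAATTTCGA
TGCAATCAAACACTCGTACGCCCGATAAGAGGCGATCACGTTTTAGAGTCATTAACTTATCGATGCCTCG
CGAAACCAGGTCCAGCCGCAGGACCGAAGACAAGTCCTTGCAGGGTAACTAGATTGAGCGGCAGGGTTGA
GAAC
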