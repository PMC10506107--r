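>synthetic_tx_long
AACGGACGATGCGTGTATGGCTGTGAGACTAAGCTCTACTCGAAACATCTTTCGTGCCACATAAGTGCAAGCTCAATCTA
CTCATATCGCTTCCGACGCCCCGCGCTATATCATTCAGGACTTGAGCTCAGTTCAATAAATTATAAAACTCCGTTCCGGG
CAGTCAAGAAACACGTTGTTATCGACTGGCAGGAGCAATACGATTCCAGAGTGACAGAGCGCCGCAGCTGGTCAGCTACG
CCATACCCCGAGATCTGGACCCGGGGAGGTGTTGATCCCATAGATGATAGTTCTGAATTGCAGCTCGTCGTTCGGGAGGA
CCAATGTGAAATTTGAACTAAGAGTATCCTGCTCCCATTTCGTGAACCGGCCTCGAGAGCAATGGAGTCTTCTCCGTGGT
ATGCAAGAACTCGTACTTTATCAAATCTGGAATCTAGGGATGAACCGTTTGCGTTCTCTCGTGCCGAGTCACGGACGTAT
TCGTATGCGAAATGGTGCGATCGCGCCTCTGCGGAGAGCCCGGGCCGTGTACGTGGGATCCTTGGGTGCCATATTCCAGG
GCAGAATTTAACATCGTGTGGTCGTAAGCTTAGTAACCCGCATTAACCTGGTGAAGTAGTAATGATAGGATCTCACACTA
CATTTTTGCAATCCTCACGATCTTTATCCCTGGAGATAAGTTGGGAGGTGCCACCAATAGCAGGGGCTTGGCGAGTGAGC
TGTGAGTGACCGACGAGTGTGTCGATCTGCTTCTACTACTAAGAAGTGCGCCCCCGAATCTACGCTTGGTGGCTACCGCA
CTCAAGGTGTAATCCCTTAAGCCAAGAGCAAATATACGACCAATCTAAGGAACGGCCGTGAAAGGATCTCTGACTATCAC
AACCGTGAATGTCAGATGGATCTAGA
>synthetic_tx_short
GCATTGATCTGGGAGGCGATTTTATACGGCCGTTTGATAGGTGGGTTGACTAGACGGCTTCACTCTATGACGCACCAGTG
AGGGGTTCGCTTAACGAAATACTCTAGCCGGGAACCACCCGGGCCCGTGGGACAAGATTATTTACCGCGAGCATCCCTCC
ACAACGCGCGTATCAACCTTCCGCACCAGTACGTTCCCGCGGTTGTGCTACGTGTACACACATGGGCACACTCAGGAACG
ACTCATAGCGACTGACAATTTTGTCTTCATTTCAACGTGCGCAGCGTGCATAGGATCTGGTAAACTTTTACCATATATCC
TCCCCGATCTCTATGTCCCCATAGCTATATCGAGCTGATTCTTCTGGTAGGGCATGGTATAACCCGTTAGTTGAATATAT
TAAGTCGGGAGAGGAATGTGGATGAGTAGCTACTGCCGGCACGAAAGAATTGC
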