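>recA_synth
ACGTCTTTTAGGCAGAGCTGCAGCGCGACATAGGGCGAAATCTCTTGTAATTGCGCTGCGGTACCGGTCC
GTTAAATGGACGACGTGTACATATTCCTTTTAAGTATCTTTCTCCCTCCCCAAAGTCCATGATCATTGCC
ACAACACGCCAGAACGCGGACTTTATACTCGTAATTTGTGGCGTTCGAAAAATAACTGGTGATTCTTTTT
GAGTTTAAAATTAAAGCCTGTTCTTCCGCTAACAAGCGAATAAACCGCGACACTCGCTATTTCCTTAGGT
TTGTTGCCCTGAATTCACGTTTGCGCCGCTCGAGACGGCACAGGTAAACCGGGTGTCAATATTAATATAC
CTCTAAATTCCTTCTTTTTATAATGTCAAAGCGATTTCACGGTCGAGGATGCTGTTTGATCATTTTCGAA
TGAGAGACTAAGGCAAGTGGATCACAGATGAGTAGTAAGGATCAGATTTCACAGGACAACCTACTTCCCT
TCCCTCCTTGCGTTGAGTAACCGGAGTGGCGGCGCTCACTCATTGCGTCGAAAGCGATTAGCACATCGTA
AAATTTTCACGAACGTCGTAAATTAATCGGAAGCTGAGCCGCTAGATTTCTCGACCTTTTCTTGCAGTTT
GTTCCGTCGAGCCCGTCCATTTTTAGGAGCAGCAAGCTAGTTTCTAGGGGCTCCGGCGTTTCCGTCCGTT
ACGTAGGAAGCTTCCCATAGTTCATAGACTTTCCAATACCTATCTGACTGGAGGACCAAGAATGTCTGGT
AAAGTGCATTGACCGAAGATCGCATAGCGGTGTAAGTACTGAACCGACCTAGGAAAACTGCGGATCCATC
ATCTGGTATTTAAAACAACAGGCTCACTGCTTAGCCTCGTCCACCTGGGCAGGAGGGCGT
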