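>radA_synth
CACACAATGCCTCCGGCATTATAGGAAACCGTTTCGCCAGTCTTGTACATAATAAGGGATCGCCTTTCAC
GGGGAGGGAGTGTTAAAAGAGTCGTGACTTTGGGCGGCTCGAACTGAACACCACCTTTTGATAGGAGATC
TTGGTCTACACGAGCGGGCCCAGTTTGTCCTAGCTACCCAGTCATGGCGCATTTATACGTGTTATGCAAC
AGACGTTTATCACAGCATAACTGCGCATAGCTTCGACTGCCTGATTCGCTAACAAACCGGGTCTCGGCGG
CTATAGGAACTGACGGCAGTGCTCATGTCTCTAGTGACTACCTCTGACATCGGGAAACGGTATACGCTGA
GTGCAGTGGCACCGCTGCCTGTAAGATTCGGCAACATACGAAATACTGGAGATGACTAAGTTCTATGCTC
CATCAATTTCGCCTTTCGATTTTACTCTGTACAAGTACATAAGCTAGTTGATGACCAGGCACCGTAACTA
CACGATAGCCGCTAGATCACTTCATACATCGAGTTAAATAGCTTCACATTAAACAAGGTTAACAAGGTTC
TATTTGCGCATGCCTGGGCAGAGCTATCCGTGCATACGATATTGCTATTGAGTAACTCGGGTACCCAATT
GGAATATGCTCTAATGTATGATAGACGCAAAATTGTGAGTATCGTGGACCTATTCTAACTTGTATAGATT
CTGGAACATAGATGATGATAGGAGGGGTTACTATAACGTGTATTAATACAAATAGGTTTGCAGCACACCA
GTTTCTATACACCCCGGGGCTAGCAGAGCTAGGCCTCCTTTGCAGGCTAGGGCGTCTGGATCCGAGTTGC
TCGCACAAATCACTTATTATTGCCATAATCCGTTTCGCCGCTTGATGCGGTTGTTCGGTT
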