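>green
GATCATGGTCTGGAAATTCATTCTCGTATTAAAGGTAAAAAACATCCTGCTCAGGAAATGAAAGTTCCTG
AACCTCGTCGTCTGATGGCTTGTGATACTTGGAAAGTTACTATTCATCTGTGTAAAGGTTTTGTTTATGA
TGATGGTGCTTGTGAATCTCCTTATCATACTTGTCGTGAACAGAAACAGGAAGATACTTTTTGTGGTTGT
GAAATGAAACGTAAATGTATGGTTACTGGTTCTGATTATCAGCGTGCTCTGCGTGATTATATTTGTGATC
GTCGTCTGGTTCCTACTCATCAGTCTGAAACTCTGCCTATTAATCAGTTTTTTCAGGCTGAAACTAAAAT
GGGTGGTGATTTTGATCCTATTGATACTCGTTTTACTCATAATTATATTCTGGAACTGACTGGTTTTTGG
ATTACTCTGCCTCAGACTTGTCATATTACTTCTGTTATGCCTCAGTCTGCTATTGTTACTAAATTTCATG
CTATGATTTCTCTGTTTCGTTGTGCTTATCATATGGCTCGTTGTTATCGTATGTCTTCTCCTCAGATGAT
TCAGATTGTTTTTATTCAGCAGCATATTAATCTGGTTAATAAAGCTCGTGCTCAGTATAAAGCTAATTAT
GAAGTTACTTCTAATTGGTATTGTTTTCCTCGTTATAAATATATGCGTGAATATGATCAGCCTGTTCCTG
AAGTTGTTCCTGAATATTGT
>blue
GATCATGGTCTGGAAATTCATTCTCGTATTAAAGGTAAAAAAAAACGTGCTCAGGAAATGAAAGTTAAAG
AACCTCGTCGTCTGATGGCTTGTGATACTTGGATGGTTACTATTCATCTGGAACAGGGTTTTGTTTATGA
TGATGGTGCTTGTGAATCTCCTTATCATACTTGTCGTGAACAGAAACAGGAAGATACTTTTTGTGGTTGT
GAAATGAAAAATAAATGTATGGTTACTGGTTCTGATTATCAGCGTGCTCTGCGTGATTATATTTGTGATC
GTCGTCTGGTTCCTACTCATCAGATTGAAACTCAGCCTATTAATCAGTTTTTTCAGGCTGAAACTAAAAT
GGGTTTTGATTTTGATCCTATTGATACTCGTTTTACTCATAATTATATTCTGGAACTGACTGGTTTTTGG
ATTACTCTGCCTCAGACTTGTCATATTACTTCTCCTATGCCTCAGTCTGCTATTGTTACTATGTTTCATG
CTATGATTTCTAATTTTCGTTGTGCTAATCATATGGCTCGTTGTTATCGTATGTCTTCTCCTCAGATGAT
TCAGATTGTTTTTATTCAGCAGCATATTAATCTGGTTAATAAAGCTCGTGCTCAGTATAAAGCTAATTAT
GAAGTTACTTCTAATTGGTATTGTTTTCCTCGTTATAAATATATGCGTGAAAATGATCAGCCTGTTCCTG
AAGTTGTTCCTGAATATTGT
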