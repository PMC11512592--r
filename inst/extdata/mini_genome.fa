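>mini_mt synthetic 2000 bp circular mini mitochondrial genome
CAGTTTCTTACGTGAGGAATACGAAAGCCGATGGGTTATGGTGTCGCGTAGACTCGGTCGCTCCTCCCAAGACTATCTTC
CCGAAACTATTTGGCATTTTTAGGTCTTAGAATACTACCCCTGGCCTAGCCCGTTTTTCCACTTATAGGCGCACCTTTTT
CCTAGCTATAGCGGCAGCTCCTATTGACTTACAATATGCTGGTGTAATGCCCGCGGGACAGACACCCCATCCTTACAGAA
TCAAGCTGATGCCACGATCGTTCAGGTCTCACTACCGTATTTGCCCCCTCTGTCTGACGGCTAAATTTGCACTACTGTGT
TAGCAAGTACTTGCTAGGGAATGCTCCCCCTCTTCAGCTCTTCGCATCTTTAAGGATAAGTCAGCCGGCCAGTTACTATA
CGGGGTTATTGACATACGCGCGTTGTTTACGCCGGAATAGCCCTAGCCATGGAGCTACCATAGTTAACGAATGGCTACCG
TCGTGGATGAACAACAGAGCGAACACTACACGAATACTCAAACCATGCGTATGCTATCGCCCAACGTGATACAACTTATT
GATTCCTCGTCGCTCCGACATCGCGTACCTCCCACGGCCCCGGAAAGTTCTTTCTAGCGCCGTAGACATAAGGAGTCGAT
CAGGTCATATAGTTGATTTCTAGATCGTCTAGTTGGGGAAGCTTGTTCAGGATCGGCGCTATGACTACGAGGAATCTAGA
CACCTTAGCGAACAGGGTATAAAGACCACACAGAGATGTACGCAGAATCCATGGCAACGGTATAACACGTAGGTTGGTGC
CAACTTCACGAGAGTGCAGGTGGTGGGGCGCAGGCAATGGGAAGTACTCGGGTTCATAAACAGGCTTACAATTGGGAATC
ATGTATGTAACGAGCGTTGGAGAGAGATTTATAGCAGCTTCATACAATCACTCTATATCGGGAGGGGACATAATTCATTT
GTCTGCGGCTATAGCTAGCTCGTTAGATGTGCCGCATGGAAATGTAAGTCCAGTGCACCAGCCGCGGCCGGTGTGGCCGA
TGCTTAGTACCCGAAATAAAGAGACCACGACACTGCCGGTCGTTGTGCTGCGCCGTCTTGTCTACGGAGCCGCACTATCG
TCTTAGGAAAGGGTCTGCCAAGGCCCGATAGAGTGACCCAAACTCTTTCAAATGCGGGTTCCGCCATGGACTCCGGGTCG
TGAGTATTCGGCTCCTGTCTGGTTCCACGGCGAACTCTCGAAAACGCTACAAGAGGGCTGTACCGCTGCACCGTAACTGA
ACCCAAACGACTATCTAGCTCACAGATACCGTAACATGTCGGTGGATTACTGGGCGCCTCCCGACATACCGTCGCTGGAC
AATGAAACATCTGTAACGAAGATCTTACAACTACACTTTACGAAAGATGCAATGTCTTCGACTTGAATGTGTAGGCCTCA
AATGAGGAGCGGAAATATACGTTGTAGCGTGTATGTTTTTAAAACGGCCCACTTGATCGCATGGCAAAAAATTTGGTACC
GACCACACCAGTGAATGTATACTTAGTCATCACGGTCAATTATAGCCCCCAAGGAGTTCGTTTGAGGCGGGGCGTAGCTT
GGATGGATAGGAGAAATTTTCTTAGCTGTCAAGGAGGTGTGTTAGTACCAGCGGGTTGCGTATAACAACCGCTTAAACGT
CACTTTTGCACTCGCTAGTTAATATGCAGGGAACCTGAGTAAAGGCCAGATACCCCACATAAGAATTAAGTTGACAGCCA
GCACAGCTGGGCGCCTGGATGGAGGAGCTAGTTTCTACGAATGATTAGAACGAGAAAGAAGTCAGTACCAAGTTTGCACA
CATATCAAGACGCGTTTCAAGCTCTCAACGTCCCGCGACCTTCAAAACCTTGGGCGTGCCTGCGCGCTATCGTGCAATAA
ATCTCATCTGTTACTCATCGAGATCTTGTTCGGTTCGAGACAGCTCCGGTCTTACCCGCCTTTGAGGCGGCATAGGCACT
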