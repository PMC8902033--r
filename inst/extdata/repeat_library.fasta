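>telomere_TTTAGGG_array_synthetic
TTTAGGGTTTAGGGTTTAGGGTTTAGGGTTTAGGGTTTAGGGTTTAGGGTTTAGGGTTTA
GGGTTTAGGGTTTAGGGTTTAGGGTTTAGGGTTTAGGGTTTAGGGTTTAGGGTTTAGGGT
TTAGGGTTTAGGGTTTAGGGTTTAGGGTTTAGGGTTTAGGGTTTAGGGTTTAGGGTTTAG
GGTTTAGGGTTTAGGGTTTAGGGTTTAGGG
>satellite140_consensus_synthetic
TTCTAAACTAACGGTGTCGCGCGAGCCATGCGACCGCTTGCCAGGTGCTTCTGTGATATG
TAAACTAGCTCAAATGGTGGTGTGATATGAAGTCAAGCTTGAGTCTTAGAGCAAGGAAGT
GTCTTAACAGTGCTCTGAGA
>rdna_unit_synthetic
CGCGTGTGTGATTACATCATACTAGCGCGGGTTGTAAATGTTGACCGGCCCTCAGAGGAG
TAGGGCTCCCAGGACAGCTCAGCGGCAATGGGGACGCTCCTGGAACTCACAGCTCGTCGA
ATAACAGTAGCAATACTTTCATCGAGTTGTGCAGTGAGAGGGATGTTAGGAATGGGTTGT
GATTATCTCGATTTCGGCCGCCGAGTGCCAGGGCCAATACTAAAACCGGATTAGGAAAGT
TAGGTCAATGCCATTGTTTCCTTGGTTGTGCGACCACCTTGGATACACCCTCAGACCCGT
CTCTTGTCGCCAAATTCGACCTATACGAGCGTCTGGGCTGTAGCGCCTTAGACGAAGATA
ACAAGAGAGACAGTACAGTCGGGCAGGTATAAAAAGTGAGCCGCTCCTAAGGGGCCTAGG
CTAATATTCTGTTTAGGGTACAATTGTGACTGATTGATACAGGTCATCGGTCCATCGGCT
GCTTAATGGCTAAAGAGCCTCAGCCGAGTGCTCTTCAAAATAATGGTCGCAATAGAAGGA
ATAGTGAAAGTTATCCCTGGCCTTTTGGACGCGAAAAACACGTGGCGACGGGCCGCCCGA
TCGCAGCCCGGGGGGGGACGAAAACCTGGAGCGGTCTGTGGCGAGCGTCTCTTCTTCTTG
GACTGGAACTACAAGGGCTAACGATCCCCACCACAGGGACAGGTCGCCAAGTTTAGGCGG
CCACTTCCATCGATCTACTCGATGCTCTATTAGTACGTTCGTTTGGCCAGGAGCAACGGC
AAATAGCCTCGCACGGCTACCCGAATACATGCTCCCTCTTAATCTACGACAGGGAGTCGC
CAGACTAAAGTCACATTGTCCTAGAACTAGGAACATACTACATACGCCTTTGTGTGTTCC
GCGTAGAGAACGCACACGTCGTTTGTGGAGGGACGCAGCTACAGATGGCCCGGTAATTCG
CGCCGCTCTGAGAGAAACCACAAGTTTCTGCCAACGTATTCCAGCCGCCGAGTGTTGTCC
ATGACAGCCATTTGGCCGATGGCCGGTATCTGTTTAGATAGTGGCTAAGCTGGTCCCCTG
ATTGCAAAGCTGGGGAAGGGCAATGCCTTGTCTTCTCGGAATAAAGCAAAGACACCTATT
AGGTGAGAGTCATAAGTTTTTGTCTCTGCAGTGATCCTGGTGTTCGATGATTGCCGCACC
TTCAAGCGACGGTGTCTCGAGTCCTCTTCCCGGGCGTCACGAGGAGTGTGATGCGGTTCG
TAGTTTATCATCGTCGTGGTGCTTGAGCTTAGTTATCATCAGGGATCCGAGGCTCGTACT
GGACGTAAAAGCATCCTCCCTATAGGTCGGTGTGGGGGGTCCTTGCTAGACTCGAAGACT
AGCTCTCTGTAATGCCCGACCAACAGTGGGAGGACATCATGAAGGTAACGACGCCATCCT
GGAGCCACACGCCGCCGAACACTAACACACTCATAGCGGTTCGGCAAGTGGTAATATCCC
TCGACCGAAGGCTTACCTTGCAGCCCTAGCCCAGTGAGATTTTATGCCGAAGTATCGTAC
AGGCCTACCAGTGAAAGTTGTCTCTAAGCTGGAGAGAAAGGTCTTAACTTCATTCTCATG
CTCAGGCTGTGATTTTTTTACGCTGACTAGGCTAACCCCACAAAACAAGGGCAAGGTGCA
CATGTATCCAACCGGGCAGTATTAGAGAGGGGGCGCGCGTAAGTTGCGGACACGAGTTAG
TACCTGCTAATGTGGGGTCTCTAAACGAAAGTCAGAGACACATGAGGCCAAGACCTTCAT
GTGCGCGCAGCGTATTACCAGTCTTTATTTCTAACACCCCCTCTTTCTAAGGAATGATAA
CTGAAGGTCCTGATATCGTAAAGAACGTTGACGGGAATCAACACGTCGCCGGCCCATTTA
CCAAGATCCTCTTTTCCGACAGGGACGCAGTTTACCAACTCACAAGTTTCAAAGTCTTAG
GCACCGCGAAGAGGTAGAGTTTTTACATCACGCGACGAAGAAAAACGGAATGATCAGAAT
ACCCGCAGAGACCTGATTACGCTAATTTAATATAGACTGAAGATATTTCGTGAGCGTACA
TGTGGGTTCGTACCTAATAACGAGGTAGATTGACCACCTCCTCGCAATGTCAACAACATT
TGCAAGCCTTACGAAGCGGTGGTCCTAGAACCATGCCTTGCGCAGTTTTGCGCATGAGGT
TCCAGCCTTACGAGCCGGCCTGGTCTTCCGACGGTTCAGCTGGGTGACAAGCTAGGAGTA
TTTCCGGGCAGTCAACTAGCAGCGCACTTTGATCCCCTGTAATTATTGAAACTCGTCCAA
AAAATATAGTAAATTTGGGGCTTTCTCAATAGGCGGCGGGTATAGAGCACGCATCATGCC
CAGGACACTACTTCTTGCCGGAGTTTATTCAATCATTGGGTACCATGATATGGACTGGGC
ACTTATCGCATCTAAAAAAACGTTGAACGGGAAACCTACACCGCATCCTACGCGGGGAGA
ACGCGATATAGTCCTATCTACATGGTCGCCTCAGAGTGCACGACGGCCTTCGGTCTATAA
GAGATCGATCGTCCCGTTCGGGCGGCGATTACGTGTTAAGGCGCTTACGTGTCTCGTGTT
GAATCTAATAGCCGTTGCATCGCGGAAAACCACGCAAGCCAACCGCGTGATGGACTTTAA
GCTTTTCTGGTTGTCCTATGGACAAGCCGGGACCATAAAAACACCGGTAGTACAGTAATA
CTTGAACGGGTCCAGGGTCCTTGCCCACCTGAAATATAATAAACGTGGGATTTCTAACAT
GCCACGGGCCCGTGCACCGTGTTCATCGCGCATGACGACAATCAGAATGTCATTCATACA
GCAGCGGCGGGAGGCGAATTGGCGAAGTTACGGGCATTTCAGTGAACGGACCTGTGCGAG
ATATCCAGGTACGGTAAACCTACTTCCTGCGCGACACATAAAGCATAGCCTCGGACTACA
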