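>L01
GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGT
CGACGGCGAGCAGTTGAATTTGGAGAACCTATGGGAACCGTTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTG
GAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATAGAAATAAAGAGTCTAAGTACGTCTTCCCAG
TGATCATCATTTATGCTCTACGTGGGCAGAGTGCCATATGTACTGTCTGTGCGTACTTACCGCACTTACCTCC
>L02
AGCGCTCTACCCAAGGATCTTTGTCTATTGGTGTCCAAAGAACTTAGTGGCGGCGGCCCTAGTCTCAGTACGTCTCGGGC
CGCACAAGGAGCCTAACAACCTCCGCAGAGAATTATCCTGCGCAGTCCACAGACTAGTACGGTCTGCGGCTAGTTATCCT
CCGAGGGAGCACTGGAGCTGGGTGACCTTCTTACGGCTACTCACCATGTACTAACCAATCTCTGGGAAACAACAGCGAGC
CCCAATACGTCGACTACTGATACCTCGTCTCTTGCCCTTTGTCAGCTTAAGCTGGATACCGACCTTGTCCGGC
>L03
TGTACCTCGCACCCCCGGTAAGCCGGACGTGATTCGGGTCTGACGACAAGGCGAGGACCCGTCAAGGTAAGGGCCCCTTT
GCGGGGCGAGAACGTCATGGGCGATATGGCGTCGACGCGGCACGGGAATCGCTGCAACTGTTGGCCCGGATGCCTGGTTG
TGGCAGTTGCGGAGCCACCCGTCTAGCAAATGAGGAGCGTTAGATATGGGCCAAGGCAGTGCACATCGCGGACGCGGCAT
TCTAGAACTACGTAACCTGGGTTTAATGCGGTTCGGCCAGAGGTCTAGCAACGTTCGGGTGCTCCCTTCTATA
>L04
CGTCTAGGTAGCTGAAAAAAACATAGAAATGTCGTTATATCTGAGTCCGCGACGTCAGGAGTTATGCGAGCAATAGCAGA
TGCTGTCGGGCGTCTAGATCAAGCTTACCCCGCAGGCACCTGGGCGCCAGCTTCCCGGGAGATCCAGTTGTGCACGTTAT
AGGAACAATACCTGGATTCAACGAGGAGGGCCCGGCTGGGCTAGAAACAAAAAGACTCGGAACTGTAGCGTTAGCTATTT
GGTAATTTGCCTATCTATATCCCACCGACTGGTAATTGCCTAATCTGTGCCAAATGTGGATGCTACCCTACAG
>L05
AGAGCTGTCTCAGCATATCATTCCCGTGAGCTTGGAGATGCTGACTCCCTATCCCTGGAAGCCAAAAGAAAGCAATGATA
ATTGGTGCCAATTACCACTGCCGAGTATGTAGTTTAGTTGAACTCGATGCCGTAAAGCCACGCGCAACGATGGCAAGTAA
TCTTAGCTGTTGGTACTCCGTGACCTACAGAGCACTTCGCGCTGCGCAGTTAAACCCGTGTCAGCACACCTAAGCGTGTG
GGGGAGCATTGGACTTGCGCGGGGCTTTGCGGAGGCGGGTGCAGGGGATAGGGCTTAGTGCGTGGGGGGCAGC
>L06
CGATTTGTCCTATACAGTATGATGAGATGACACCTGCAATACATGTCATGTCGTCCTACAGAGCCTGTTCCGAGGTCGTA
TATCATGGCACGTATGTCATAAGCGCCCACCACGAGTACTAGCTTCCTATTGCTGGCTTATACTGCTTAAATCGCGGGTC
TAATACCAATCCCCGGAGGAACCGGTTACGTTAGGAACGAGGGCTTCATAGAGCGAAAAGTACATGTGGAGAACCCCTCC
ACACCCAAGCACTAGCGTTTCGTTTTTGACATCAAACTTGTAAGGACAGGTGGAACCTATTTGGACAACGCAT
>L07
GAGCGAAACTCCATAATCCCCAACCTGAGCTAAAAGAAAGTATATTCTCCCGGCGGGCTAACTAGATTCTGGGATGGTTT
GGGGGACCCTCCGTGTCTACTCAATAATACTGGAAATGCCCCAAAGCCCCCAACGTGGATGTTCCCTAGCCGGCTCTTGA
CAAGGGTCATCCCTCTTAGAATTTAGCTCGTTTGCGCTTGATCGAAATTTTATCCAATTTCCAGCTGTCTTAAGCTGTTC
CGTCGAATACCCTGTATTCCAACTGCGAGCGTCAAACTACCCAATCGCTCGCCGAATGTTGCCCCCGAGACTA
>L08
CTTGTGATGTAAGGCCCTGGTCTCGATGACCACACCCGCAATCTCAATTGGTTACCCGGATCGGAGATTATTGGCAAAGG
AGGTGGAGCTGCCCTTGGACACGGAATCCACATGTATCATTTTTTAAGAGGGCAAAATATAAGTCAGATTTCACGTATTA
CGGCAACTTATTGCCACACTGCGTTGCCAATGTCCCTCTCTGCGTTTTGCAGCAGGAGTCCAACAGGGTTCCGCGTGGCT
GGTGTCTTTGAGCTGGCTCCGTCTTCTACATGAGCCTGTTTTTGATAGTATAGCCTTGCAAAAACCAAAGTTC
>L09
ATAATAGGTCCAGGATTTTCAGTAGGCGAACCCGTCAATTGGAAATCTCTTAGTCTGTGCTGCTAGACGGGGGGCGTGAA
GTCTCTGAGAAAAGGTGGGGTCTGGCCATTACAGGTGTGCCGGCATTTTTTGGCTCCTGGACTGCAAGCCTGACGGGACC
CGCTATCCGATCTACAGTAACGGATCCACGCTAGAGCGTAGAGGTAGGGCCGAGCAAATTCTGGACGTGAACGCTAGAAT
CCTGACGGTAAAGGCCTTTTCATATGGCTCGGGTTGATTTGCCTGTCACCCCTTGAATCCTTTATTTGACTCA
>L01b
GGTGCCAATGAGAGTTTTAATTGCTTTACTTGCAACCCCAGTCCTTTAGCGGACTAGTCCCTACGTCCAGCAGCTAGCGC
CGACGGCGAGCAGTTGAATTTGGAGAGCCTATAGGAACCGTTATGGTAGTTCTAATTTGTACAGATCAGAGAGATGTCCG
GAGACCGCATACCCTAGTACGTGCAAATATCAAGGCCTACGGCAGCGATAGAAATGAAGAGTCTAAGTACGTCTTCCCAG
TGATCATCATTTATGCTCTACTTGGGCAGAGTCCCATACATACCGTCTGTGCGTACCTACCGCTCTTGCGTCC
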