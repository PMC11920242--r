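>GENE001|GENE001_P
ATGAGTTCGCCGCTTATGGCATCAGTGTTCGGAAGCTACGACTTCCGGACCGCGGCGAGACGAGTCGAAGCGGCTAATAA
GCAGCGGACGCACGGACGAACCATACAGGATTACCGTCGAGACATAGCCGAAGACCTTAAATATATCGCTCTGGTTCCAT
TCATGCTGACTATTCAAAAACATGGTGACCCTCTACTACCAGGTGGAACCTCGGTCGAGGTCTCTCTTGCCACGTTCGGT
GCTGCTGCTTCGCTCAAGATGGTCGGAACTGTTCTTTACCATAAGGGGGCCCTGGCGCGCGGTCCATATCTGTTCCAGAA
CTCTTACGTGATAGTATGCAGCGGAGCGTGTGACTACCACCGACTACACTGGATCTGTTAA
>GENE002|GENE002_P
ATGGATTGGCACAACTCTGCGCTGCGTCATCTGGGCCTCCTGCGCGTTGAACAGCAACGCATGCCGCTGTTATGCGGCAA
CGAACCTAGGGGGTTATCGCTGAACGCTGTCAAGGAGGGGGTAATAGTCGGGAACAGGACGCATCTATCAAGGCAGACTA
AACTATTACTCCCCAGGTGGCCAAAGCTTGTAAACTGCATTAAAGTTCCGATCTCGGTGATATGGTTGCCTGACGTGGAA
ATGATGGAGACACGTATACCTCTGTATGCCATTACCCTCAAAGGGAGAGTCCGTCTCCACTCAGCGGGACCGCGAGACAC
CACCTTAGCACTATCTCAACACCGCCTGGCAGCGCTTGTGTGGATACTATCTGGTGGAACCGCCTCTCGTGAAGACATCA
TAGCGGTCATCTGTTGGGGTGTTTGGCGCGTTCATAGATAA
>GENE003|GENE003_P
ATGAGATACCGGACCTGTCCGGCCGGCCTGACGCCACATCGGCTGCGTGCTGTCATGGAATACGCCGACTCGCGGTTGGG
TCCGTCAGGCAGCCAAACGTTACCTGAAGCGCAGCCTATTTTAATGGTGGTCACTTGTCGTGACGTAGTCATATCGAAAA
CACAAATTGGATTATGTCCACGTTTTCGGAGTCCAGATTTTAACTTTCCCGTGCTAGTGAGGGTCCGAATCTTTGCGTGG
GAGTACAAAGCGATAGCCGCTGGGGATGCCGTCTACCTCAGCGAAGACGGGAGTACATCAGATCAGTTTCAGACAAGGCT
TGCGACGTAA
>GENE004|GENE004_P
ATGCACGTACGCAATTTTTTTTACCCTTCAACTACTCTCCTTAGTAATAAGTATTGGGCTAACTTATGCGCCAAGCGAGG
CGTGCCGCTCTTTAAAGTCAACAGATCATTCACACAATTGAGTCTATATGAACGGTCAACACCTCGCACCGTATGGATAA
CTGTGAACGTCCAGATAATAGGTTCTAGAAACTTCTCCCTAACCTATACTCCAGCTGAATTCTTAGTGGCGATCTCCGAG
GTACGGGCAGCACCGTGCGAGATCCCGACAGTGTGCGGAAAAACGGTGCGGTCCGCGCCGCAGAGGCTAGAGACAAGGCA
TGAACAGCGGATATCTGGTCCCACAGATCGTCGGTCTGCACCTGCCATGCTAAGTAGGATAATCCTAGTGGGAGACCCCC
ACTGCCGTACTAGCTAA
>GENE005|GENE005_P
ATGCATCCCAATGAAGTCAGCCCTGTGGGCAAGCATTATCTGAGGAAGAGCTTATTACGACTTAGGTCTTGGATTTGTGG
AGCAGGTAAGAGCAGTGCGTTGTTGTTCCTGAGCGCGCTTTATGAATACGCGGTGGAATCGTATTGGAGCGGATGTATGA
CGCTAAGACAACGCGATGGCGTAGATATGCCTAGACTCACCGCCTGGGAGGCACGAGAGATACCTAATGCGGCCCCGTCT
AAGACCCCGACTTGTCTACCACGCGGGAGAAGCTCCATTATGACAGAGGACGTTATGAGATACTGGTGTAATAGCTCCAC
TATCTCCCCAGTTGATCGACGGATCGGATCCGGGTGTAGTAGCTCGTCGAACACCGAAAACATGAACCTACTCAACAAGG
TACTAGGCCAGCTATGGGCTCTTAGCATGATTTCATGGACTTAA
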