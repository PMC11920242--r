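GAATATTCAAAAATTAGGCC
CATGAGGGGCCAATAAGGAC
CCTCTCACACACGTCTCACG
ATGGGGTAAAGATAAATAGG
GGGGCTGTCCCAGACTATCC
TCGAGTAAATCGGTTTTGTC
AAGGGCGTGGTGGGACATTA
ATCGCCTGCAGGAAGTCCAC
TCGTGGTGGGTATAGGCCTA
TGAGGTCAAACTATCAATTG
TACAGTCCATGTATACTTGT
TGGCCGTTTATCGTGAGTTA
GCCCAATACGCGACAGTGAC
TGGAGGTGTCACCCAATAGT
GAGACAGGAGGATACGCCTG
AAAATAGCCTCTATATCTTA
CCACTTTTCAGGCAGTCAGA
TCACACTATCTTCGCCCTAC
TCAGAGTGACAACCTGACAT
TATCCATTCCACAGGTTACT
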