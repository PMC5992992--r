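>synthetic_wt_amplicon_185bp
ATACGCGCGCAGTTAGCAGCCGATCTCCCCAAGCGCTAATTATCGGCGATAGCGCTGTAAAGGGGCCAGGGACTTGTGTGTGATATCATTGCAGGTCGCGGTAATTAGTGAGGAGTCCCTTATGCCTCCCTGGACGTAATGCCTTAGTACTGATAATACATTATTCAACCAGCTCATTGCTAGTC
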