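>human
ATGCGATGTAATAAGCGTGACATTAAGTTTGTTCTTAGTCCGGAACAGCGACAGCCGCCG
ACGGCTAAGGTTAAGTCTCTTTATTTACTAGAGTTGAAGGCAGGTTGCGATTCTATGTGC
CTGTTTTTTTCTATTGCCCCCTTAAGAAGACCCGCACGCCGGGGAGGAGGCTGCCGACAG
>rabbit
ATGCGATGTAATAAGCGTGACATTAAGTTTGTTCTTAGTCCGGACCAGCGACAGCCGCCG
ACGGCTAAGGTTAAGTCTCTTTATTTACTCGAGTTGAAGGCAGGTTGCGATTCTATGTGC
CTGTTTTTTTCTATAGCCCCCTTAAGAAGACCCGCACGCCGGGGAGGAGGCTGCCGACAG
>mouse
ATGCGATGTAATAAGCGTGCCATTAAGTTTGTTCTTAGTACGGAACAGCGACAGCCGCCA
ACGGCTAAGGTTAAGTCTCTTTATATACTAGAGTTGAAGGCAGGTTGCGCTTCTATGTGC
CTGTTTTTTACTATTGCCCCCTTAAGAAGCCCCGCACGCAGGGGAGGAGACTGCCGACAG
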