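>CD14|Homo sapiens|SYN-CD14-HS|X1
ATGCGATGTAATAAGCGTGACATTAAGTTTGTTCTTAGTCCGGAACAGCGACAGCCGCCG
ACGGCTAAGGTTAAGTCTCTTTATTTACTAGAGTTGAAGGCAGGTTGCGATTCTATGTGC
CTGTTTTTTTCTATTGCCCCCTTAAGAAGACCCGCACGCCGGGGAGGAGGCTGCCGACAG
>CD14|Oryctolagus cuniculus|SYN-CD14-OC|X1
ATGCGATGTAATAAGCGTGACATTAAGTTTGTTCTTAGTCCGGACCAGCGACAGCCGCCG
ACGGCTAAGGTTAAGTCTCTTTATTTACTCGAGTTGAAGGCAGGTTGCGATTCTATGTGC
CTGTTTTTTTCTATAGCCCCCTTAAGAAGACCCGCACGCCGGGGAGGAGGCTGCCGACAG
>CD14|Mus musculus|SYN-CD14-MM|X1
ATGCGATGTAATAAGCGTGCCATTAAGTTTGTTCTTAGTACGGAACAGCGACAGCCGCCA
ACGGCTAAGGTTAAGTCTCTTTATATACTAGAGTTGAAGGCAGGTTGCGCTTCTATGTGC
CTGTTTTTTACTATTGCCCCCTTAAGAAGCCCCGCACGCAGGGGAGGAGACTGCCGACAG
>IL10|Homo sapiens|SYN-IL10-HS|X1
ATGTCGGACAAGGTGCCGTGCCGATTTGAAGGACCCCAAAAATTGCTCTCCCACTTTAAT
CTCTTCGGCCTCGTCGTGTACCATACTGACGTGTTCTCCAGTACGCGAGGATCGAATCAA
TGTTACAACTCGCCGATACGAATGTCAGCTGACCTTGGGCCCGGTATGTGCACAACAACC
CTCATTCGTTGTTGGGGCCTAGCCTTGACTCGGTGTTTCTTCAAGATTTCGAGATCTAGG
GGCTCCTGTACCATTAGCCTTAATCACACACTATCCCCGCTACTAAACCCACTGCATCGT
>IL10|Oryctolagus cuniculus|SYN-IL10-OC|X1
ATGTCGGACAAGGTGCCGTGCCGATTTGACGGACCCCAAAAATTGCTCTCCCACTTTAAT
CTCTTCGGCCTCGTCGTGTACCATACTGACGTGTTCTCCAGTACGCGAGGATCGAATCAA
TGTTACAACTCGCCGATACGAATGTCAGACCTTGGGCCCGGTATGTGCACAACAACCCTC
ATTCGTTGTTGGGGCCTAGCCTTGACTCGGTGTTTCTTCAAGATTTCGAGATCTAGGGGC
TCCTGTACCCTTAGCCTTAATCACACACTATCCCCGCTACTAAACCCACTGCATCGT
>IL10|Mus musculus|SYN-IL10-MM|X1
ATGTCGGACAAGGTGCCGTGCCGAATTGAAGGACCCCAAAAATTGCTCACCCACTTTAAT
CTCTTCGGCCTCATCGTGTACCATACTGACGTGTTCACCAGTACGCGAGGATCGAATCAA
AGTTACAACTCGCCGATACGAATGACAGCTGACCTTGGGCCCGGTATGAGCACAACAACC
CTCATTCGTTGTAGGGGCCTAGCCTTGACTCGGTGTATCTTCAAGATTTCGAGATCTAGG
AGCTCCTGTACCATTAGCCTTAATAACACACTATCCCCGCTACTAAACACACTGCATCGT
>TLR5|Homo sapiens|SYN-TLR5-HS|X1
ATGTACCCCACACTTTGTCTCTGGGTACTGGAATCAGGTAACACCGATTACAGGAAATTA
CTGGCTCGCCCTTTGGGGTATTGTCCACCAGCTATTCGAGGGTTGTCATTATCAGAGTCG
ATAGATCTGCCAGTTCTACTGGCTAAAAGT
>TLR5|Oryctolagus cuniculus|SYN-TLR5-OC|X1
ATGTACCCCACACTTTGTCTCTGGGTACTGGAATCAGGTAACACCGATTACAGGAAATTA
CTGGCTCGCCCTTTGGGGTATTGTCCACCAGCTATTCGAGGGTTGTCATTATCAGAGTCG
ATAGATCTGCCAGTTCTACTGGCTAAAAGT
>TLR5|Mus musculus|SYN-TLR5-MM|X1
ATGTACCCCACACTTTGTCTCTGGGTACTGGAATCAGGTAACACCGATTACAGGAAATTA
CTGGCTCGCCCTTTGGGGTATTGTCCACCAGCTATTCGAGGGTTGTCATTATCAGAGTCG
ATAGATCTGCCAGTTCTACTGGCTAAAAGT
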