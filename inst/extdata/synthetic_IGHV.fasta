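>X00000|IGHV1-18*01|Homo sapiens|synthetic
TGTAAAAAAGGTTTGCATCGTTGTTACGTGGCTCCCATGTGGCGTCGCGATAAAAATCATCAACATACGGAACATACTATGGGTTTCGGA............ATGAACCTGGATAATCAATGGCCTCTTACGCACATCTGCTATTATTGGGATGATAGAATGTATCAGAGAGAAAAC......ATCAAAGTCGAGTGGTATCAATGGACCATGAGTACAGGGTGTGATTCCGGATGGTTTTGGATCCCGGCGTGTTGGTCTAGGTGGTTGATTCCTCACTCTCACGGTATGGGACCACGTGACCCACGATGC
>X00000|IGHV3-23*01|Homo sapiens|synthetic
TGCAAGAAACGTAGGGTTGATGATCACGTGGCTCCACTTCGTGTCCGTGATGTGAACCGCTTGCATGACCACGGGACCTATATGCGAGCCGGG......GAGCAGCCGGTCGGAAATCAGTGGCCCCCTACTGTTGCATGTTACTCATGGTGTGATAGAATGTATGAGTATCCGCCGACGCCTTCGAAAGACCATTGGTATCAGTGGTGGTGGTTTAGGGTATGTCGTTCCGACTGTTCAGTGTTGATTGCGAACTGGTCATGGAAACAAATTAAGCATCTGCACGGACGCTGGCCGCGAGATCCTCGTTGC
>X00000|IGHV3-7*01|Homo sapiens|synthetic
TGTAAGAAACCCCGTGATCGATACTACCAAGCTCCGCTTTGCGTCAAACGGGTGAATCATTATCACCCAATGAATACGAATCAGGCGATCATGAAAAGAGAAAATGAAGTGCATAACCAGTGGCCACTGATACTCCGTCACCAATACTCAGACGATAGGATGTACGAGTTCACGGCG......GATGTTGAATTCTGGTACCAGTGGACGGCCTTTGATCTCAAGCATAATGGCCACCTTGACTGGCCGGGCTGTGACTATTGGTGGCAAGATTTTCACGACCCGGGACATGGGCCAAGGGACCCACGCTGC
>X00000|IGHV4-34*01|Homo sapiens|synthetic
TGCAAGAAACAAGTTGATTTCAAAATCTTCATTCCAATGTGTTACAATGAACAGGAACATTATCATGCAGTGTATACAGAAGGTTATGCG............GGCAAGGGTAGAAATCAGTGGCCCACAATCATGCATCATCAGGATTTAATGGATAGGATGTACATGATCGAGCGCTACGATTACAAGCACATATGGTACCAGTGGTCGACAATGATGGGGTGCCATAACGGATGTCCTTGCCAAACGGCCTGCGACGGTTGGGCGTTAATACCTTACGATCACGGGATGCATCCTCGGGATCCGCGATGC
>X00000|IGHV4-39*01|Homo sapiens|synthetic
TGCAAAAAGGGTAATGTCTTCGATATAAAGTGGCCACTGCGTGCACGCGACGTCGAAGTATATCATCGTTTCTTGACACTGATAAGACTGTCG......CCTATCTCTCACATCAATCAATGGCCTATAGTCATGATTTGTAGGGACGAGATGGACCGTATGTATGTCCACTTGGTG......TCTCGTTTGCGTTGGTACCAGTGGACCATGGTGGACGGGTGTGATAATGACTGTTTTTGCATACCGGCAACTGATGGGTGGTGGCAAGACTTCTATAAGGTAAGGCAAGGTTGGCGGGACCCCCGATGT
>X00000|IGHV5-51*01|Homo sapiens|synthetic
TGCAAAAAACCCGTTGTGCGCGATCATTTCATTATCGGTATGGCCGCTCGGAAAAACTGCCAACATGACGAAGGGACTATGCATATGCTTGAGGAGGATTCAAATTACGAATCAAACCAGTGGCCATTAACCCTACGTTGGCGTTCGTGGTGTGATCGCATGTATAATACGGATCGACAGTCCAGGCATAACTTATGGTACCAATGGTCTATGATGACAGTTAAGTGGCGCGACTGGTCCGTCCAAGCATACTGTTGGGGTGATGCTCAGATCCATGACTCGGTGTATCAATGGCCCCGCGACCCGCGGTGC
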