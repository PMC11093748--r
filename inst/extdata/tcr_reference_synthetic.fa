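>SYN00001|TRAV1*01|Mus musculus|F|V-REGION|synthetic toy reference
ATGAAGACTGTCACCGGCCCCCTGCTTCTCTCAGTCTTGTTACAGGCTTCAGTGCAGGGCCAGTCGGTGA
CTCAAACTGAGGGACCCGTCACACTGCCTGAGCGGGCGGCCTTGACCCTAAACTGCACTTACCAG
>SYN00002|TRAV2*01|Mus musculus|F|V-REGION|synthetic toy reference
ATGAACAGTTCTCTGGACTTTCTGATACTCGGTCTTCCATTCAAGTCAGTCCAGGGTGATTCAGTCACAC
AGACCGAGGGCCTCGTGACACTCACGGAGGGTTTACCTGTGATGCTTAACTGTACATACCAG
>SYN00003|TRAJ12*01|Mus musculus|F|J-REGION|synthetic toy reference
GGCTACAAGCTCACCTTCGGAACCGGCACCTCCCTGTTGGTTGATCCT
>SYN00004|TRAJ33*01|Mus musculus|F|J-REGION|synthetic toy reference
GACAGTAATTATCAGCTGATCTGGGGTTCCGGGACAAAGCTGATAATCAAACCT
>SYN00005|TRAC*01|Mus musculus|F|C-REGION|synthetic toy reference
GACATACAGAACCCCGAACCGGCAGTCTACCAGCTAAAGGATCCTCGCTCTCAAGACTCCACCCTTTGCC
TATTCACCGATTTTGACTCGCAG
>SYN00006|TRBV19*01|Mus musculus|F|V-REGION|synthetic toy reference
ATGTCAAACACCGCTTTCCCAGACCCCGCTTGGAACACCACCCTATTGTCGTGGGTCGCTCTGTTTCTTC
TGGGTACTAAGCATATGGAAGCCGCGGTTACACAGAGCCCCCGGAATAAAGTTGCTGTCACTGGAGGCAA
GGTGACCCTGTCATGTCAACAGACA
>SYN00007|TRBJ2-7*01|Mus musculus|F|J-REGION|synthetic toy reference
TCTTACGAGCAGTACTTCGGCCCAGGCACCAGGCTGACCGTCCTGGAA
>SYN00008|TRBC1*01|Mus musculus|F|C-REGION|synthetic toy reference
GAGGACCTGCGCAACGTGACACCTCCCAAGGTATCCTTGTTTGAACCCTCAAAGGCTGAGATCGCTCAGC
ACAAGAAAGCCACTCTGGTGTGTTTGGCACGGGGATTCTTTCCCGACCACGTGGAGTTGTCTTGGTGGGT
CAACGGCAAAGAAGTGCATTCGGGGGTGTCTACAGATCCCCAAGCTTACAAGGAGTCCAACTACAGCTAC
GCCCTCAGCAGCAGACTGAGAGTGTCAGCCACATTTTGGCACAACCCACGGAATCACTTCCGTTGTCAGG
TGCAGTTTCACGGACTGTCCGAGGAAGACAAATGGCCTGAAGGGTCCCCCAAACCAGTCACCCAGAATAT
CAGTGCTGAGGCGTGGGGTCGCGCCGAC
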