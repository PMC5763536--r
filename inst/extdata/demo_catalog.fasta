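>hY4-synthetic
AGTTCTGATAACCCACTACCATCGGACCAGCCGCGAGTGGGAATAAGCCTACTTTCTCAGTACGACGCCTCAAAATTAAA
TTTCTCAGCTTTTC
>mirna-001
TTAGTCCTGGACATCCCCCA
>mirna-002
ATTATGTGGCATTCCATAAA
>mirna-003
TAAACATGGTCCAAGATTGA
>mirna-004
TAGGAAGAGTACTAGGTATTC
>mirna-005
ATAGTGCTTCATGGAATCAA
>mirna-006
GTGATAATAAACTGCAGAAGCA
>mirna-007
CTCATCTACTAGGAAAATAATG
>mirna-008
ACTTTAGCCACGCACAGTCCACC
>yrna-001
ATGACTCGGTAATTTTTTGGCTCCCAATTGAGGACGGGACCGGGTCTTCTCGCTATCAACTCCACCCTCCCGATAGGCAT
ACGAGAATTCCGGCTC
>yrna-002
TTTCTATACGAACCTCGGTAGTCATCGACGAACCTGTGAGCAACCGGTTAAGGCTACCTTACCGATTTTCCTTGTTCTCA
AGCAATCTCCCGAACA
>yrna-003
GCCTGCGTAGATTCTCCAGGCCAAGGGGCTCGGTTGACTCAGTGAAACCTTCGACTGTAACTCTGAAACAACTCGCCTCG
AACGACAGTCGAGCAG
>trna-001
CGGATACCAGAAGTCCCCATTTTGGTACGCTCGTCTTTGTGTCACGTCCCAGTCTACATCAGTACAGTCACAT
>trna-002
GGTCCTGGACGGTACAGCGCTCAAATCATGAACCCCGCATCGAAAAATTCTCGTGGCACCACGTTCCGTAACT
>trna-003
AGTTCAGAGTAACGCGTGGTCTCGTGGCGACAAACAACACCTTAGACCTTGTCCGAATCTTGCTATGCTCATT
>rrna-001
GACATTAATCCCTGAACGCAATTCTATCGATGGTCACGTCAGGGCACAAACGCTGCTGGTTACACTATCGTAATTTCTAA
CCGGCTTCGGAGTTTAATTTACAAGTGGCCCGATCATCTA
>rrna-002
ACCATCGCAAGGGCCCGGTCAACTTGTAGGATCAAATTCGCCCGACAGTGTTACGCGTGGTATCGATGTACACCGTTAGT
ATTCAATAGTGGCCAACCGTACAGCGTCGCTCTCGATGTC
>snrna-001
CCTAGTTATCGTTGCGGTGTGAATCAGCAGGCCCTGCGATTAATTATAATACACCACTTCGGGTGGGGCTCTCCAAGTAC
TACAAGAGGTTTGCTTCAGGACCAGC
>snrna-002
TTGGGTAGAGGCACCTTTCCGTTAATAGAGGAAGCTACGGGCCATAGTCAATCAGCTTGGCGTAAGTTCATGCCCGGTCT
TGCACGGGCACGCTTCTGACCGGATA
>snorna-001
GATATAAAATGGACAAAATACTGCACTAATCCCTCCTTCTTATTTGCGGTCGCGCCCGTCGGTCAGTAGTTAGATCATGG
>snorna-002
TGGCGAAATGTGGATTCGGAACATCGTCTGTCCGGCACGCGCGAACTGTGGTGCACGATGGTTCCAGAAGAAGTACCAAA
>pirna-001
CAGCATAGGCTGCATTTTTCCGACGG
>pirna-002
AAACTACCACTTAACGGAACCGAAAG
>pirna-003
TGAGAATTACACGGTCTAACGATTCATC
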