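>FGFR1_synthetic_cds
ATGCCTGCCCTCGAATTAAGTCACACACCTCTCAAACGGGCTGCCAATGATTCCCGGGCA
ATTAATCGCTACGAGGGGTGGGGTTTGCGTCCCAAGGAGTGCCTGCAGTACAAGAATTGT
GGAAATGAACGTCACTTATTTAAAGCTCCCATAAGTAGGAATTGTACTACCCAGAAGTAT
TCGATTTTTGGCGCACTCGCTGGCGACCGTTCCTTGAATCTCTGGGCTTACGAGCTAACT
ATTAGTACACGACCACCAGTAGTCAAGGTAGCGGACCGCTTTACCAATAGCATCCTGGAA
GTGCCTTGCCGAGAGGGGCCGTGGCTGCTTGTGTACACACGAAGCGGGAACATTATACCG
GTTTCTCTGGCGCTATACGGACTTCATCGTCCAGCGTGCACTAACTCGGACGTCCGAGCA
ACACACGAGCACCTCCGCGTTAAGGCCATGACCTGTAAGAGTTCAGACTACTTACAGGAT
ATTTCGTGTCACCTTAAGACCCCGTTTCCCCAATGCGGAACAGAAGAGATTGAAATAGAT
TTAATCAATCTGACGTTGTTACCACAACAGAACGAAAGAGGTACTGGCTACCAGGACTAT
CTGGCTAAAAGACAACTGTTACGACAGCTCGAACCTTTATTGCGCCAGGGGATTCCACTG
ATCCGTGCCGGAATTGTTCATTTGTTCAGAGATTTCTTACCCCATGATAATCTGGATCTC
TCTAGCCTAGCACTGCCAGGGAATGATATGTCACGCGTCGGAGACTTTACAACGCATTAT
TCCCTTCGCTTCCGGGCGCTCGTGTTGTCGTCCCACTCCTCGAGGCAGTCTATAGTAGCC
GAGCCAATATCTCGACTTATTCTTTCCGTTAGGTACACTGCTAGACACAAATTTACGACA
CGCTCAGGGTGCGAACTACGTACCCTCGGCTCCCACGCTGCGCTGTCCAAGACCTGCCGA
ATACAGAGAGGGTGCCAAGCGTGTTATATCCTAGATTTAGGACCCTCAACGGAAGAACCT
GAAACCAGGAAGGTGCGTATAAAAGGGCACTGTCTCTATGTCTGCTGTCCAGATCTCAGT
AAGTTTGCAAGTATGGCCAGGGACGTCGACAGCACTGGGTGCTCGCGCCAACTCTCCCAT
GCTTCGGACCTTTGTCCTAGAGATCCGAAGACCAATAATAGGCGGCTCAATAAAAGAACT
CACTCCTTGAATAGCCTCCCAATAGGCTCGAAGTGGTTCTTGTCTCGACTTCGTTCCCAA
CGTATAGAGAACCTCGATCCTAGTTTTCTTGCCACCGTTGGTGGGTACACTTGGAGAGCT
CTGGTCTTGGTCTCCCGTATTGCTGACCGCACAGATGGGAAAGAAATCGTTCTGTTAGGA
CACAGAATCGATCGATATAGCAATGGAGACTCCGTACTTAGCGACGTACCAACATCCACC
CTCCTTGATTCTCTCAAGCGTTTCCCGCCGCCGAACCGCTCAGCAAATATTTCATTTACT
ATTCACCTAAAGAAACACAACAATGTCAAGAACCCATTCCCTAGCGTGCAGAGTCCAAGA
ACCCTCTCCCAGCATGGGTGCTCACTGTCACGCGCTGTTGCAGAGCGGAGTGCTGATCAC
GGCTCACCCCCACTGGATATCTGGATTTTCAATGGAAACCCTGTCGCCCATCAGCGTATA
CGGGAGCTACGCAGAAGTCAAGGGACCAGGTGGCCTCGTAAGCGGTTCTTCAAAGTGACC
ACGTATGTCGGTACTTTATCGAGAGCAAAAAGTTTATGTGCCACCGAGTCCTTTTCCGTT
AGCTCGAACCCGTCAGGGAATGATAGACATATAAAATTGGCTCGTTTGGCAGGCGTTGGA
GAATTGTACGGGGGAGGGGGATCCCGCGAGGGACCGGGCATATATGTCTCACTGTACAGA
GCCCATAGATTATGGTCGAGGACATCGCATTGGGTCTTACCAGCTATACTTCTACCCCAC
AGAAATGCAGGGGGGCAGGATGTCTGCCAATTTAACGATAAATGGTCTCTGGTCGTCCAT
GGTGCGTCCGGCTGGGAGGTGAGAGTTCAAGACCACGTAACTAAGCGGTTCTCGAGACAA
AGTGCGTGGGAAAACGGAATAGACTCTCTGGGCGACACATGTAGAAAAGCGGCGCCAGGG
GCGCTGCCGCAACTCACGCGTTTACAAAATCGACCTTCTGTACGCTTTGCTGCACTACTG
GCATGGTCTTCGATTCCAACTGAAGCCTATGAGAGATCGTGGGAGTCACTTCAGATAGAT
CTCGCGACCTCGGCCGTCCGGCCCATCACCAGTGCTCCGGGGGATAGCCGCATTGAAAGG
CCATGCATTTATCGATCACGAACCGCATCATCACCCGCAGGAGCTCCTCATATCCTAACG
CCGCCCAAGCTCTCGGAGCGGGAGGGGCAAGATCACAGTCTGGCGCGTGCGGAGGCGCGG
GTGTCGTAA
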