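>synthetic_reference
CTTTTTGGTTCTAATGCAGCGACAGTAAGATTTAAGTATCACGCATCAACACTAAAAAATCGGCACCTGCATCCTAAGAC
GGTACAGCGCTCTACCACAAAGACGTACTTACTACAGAAGATCTGAACCGTTGGCCTGGTACTTCCGAAGAGAATATAGG
TACCACATGTATATCCCTTGAGGACATTTCACATGTCACAAATAATCATATCAGGCACGGCCTCCAGAACGGGGAACGTG
TTACTCTTTGTAGAGGAAGATCGTAGGTTGTACAAATAGCAATGCGGCGGCATCATATTCCCCAATCGGAGGAGGGATCA
TTTCATCGTCAGGTCTGGTGCGCCAGCCTCGGAGAATGATACGATCCATGCCGTTCCCCACGCGTCGAACACAAGGGTAT
CAGCAGGAGGCATTCATAAGAGCATATATACACACTTCCCTCCATCAAAAACTAGAATTAACGAGGTACAAACGATCGTT
CTCTACCCTGAACGCATGAGCATTCGGCGCGAGAATAGTCTACGATTCACCGCACCAAAAAGTCACTTAGCTGAATAAAG
CGCAGGCCCACGCTATACATAGGCAAAATGACTTGCTATATGCGACAATATATGAGTAGGCTTCAAAACCTCAGCCATGC
CATTATACGCGAGCTTTGCTCTAAATTTTATTATCAGGCCATAAGCTACGAGTCCGTTGGTTCTATTTGACATGTTATTA
CTGGAGACAGTGCTCTTTGCGGATCAGGATACCCTGCGTAAGGTCAGTCTTGAGTTTACCGACGAAGCAACCATGACGAG
CACGCTGCCAGTCCCGTACTATTTGACTCGACTAATACGTTGTAGAACCAACTAACAGGCCAGATAGCCACGCCCATGCC
AACAGGCGACGCAACGTCGTCGATGCGTCCCACTGTGTAATACCACATGCTCTCACGTGGAGCAGCACTACGATTGGTCG
AAGATTTCGTTACGGCACAGAGAGTTGGGGCCTGCTGAACGGCGACACTGGAGGAGTTCTCAGCGAGGTTGGAAACGATT
GGCCCACAACACATCCTGAAGAGTCAGACCGATTTATCAGTTGTATGGTCACAAATTAACTTCATTGTCCCGCGCTCGAC
CGCATAGCACTCCTAAAGGAATCGCACGACTTGATGTCACCCTGCATCTACGGGGGGTCCGATCGATCAAGAATCCAGTG
TTGCGAAAAGTCCCCATAATGTAACCGTCTCCGATACTACACGTTATCATTGGCTACCCGACTTCTCGTGGTTTAAAAGG
TTAGGCGAAGC
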