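>BS1_mut_F PIERCE1 promoter BS1 overlap-extension mutagenesis, forward
AACAGGACGCCGCCTTGCCGCAGCAGGCACAGACTTGATCGCTTCTCCTCCAGGCACAATGT
>BS1_mut_R PIERCE1 promoter BS1 overlap-extension mutagenesis, reverse
GAGGAGAAGCGATCAAGTCTGTGCCTGCTGCGGCAAGGCGGCGTCCTGTTGCCAAGCGACGG
>BS2_mut_F PIERCE1 promoter BS2 overlap-extension mutagenesis, forward
GGCAGGTTCCAGACTTGCCTACAGCTAGCTGCCCGGCCCACGCGCGGCGCCTT
>BS2_mut_R PIERCE1 promoter BS2 overlap-extension mutagenesis, reverse
GTGGGCCGGGCAGCTAGCTGTAGGCAAGTCTGGAACCTGCCGGGCGACTCCCCAAG
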