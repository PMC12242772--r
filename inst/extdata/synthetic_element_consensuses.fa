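>e61
ACGTCCTGAATCGGATCATGCCTAGTCAGGACTTCAGATCCGGTATCACCGGAGTCAATGC
>e29
GATCCAGTCGCTAAGGTCATCGGACCTGA
>e37
CCATGATCGTACGAGTTCGACCATGGTCTAAGCGATC
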