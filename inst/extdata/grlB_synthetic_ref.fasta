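>grlB_synthetic amplicon (synthetic stand-in)
ATACCATCGATCAGGGAATCCCTAGGCCAGCGGATATCACGGTACCTGAACGATTGCAATAGGGGCTCCCCTTATCTTAGGTTTAGTAGCACGCTGATCCGCTCGATGAGCAAAAGACCGACGCAGTCCGCGCTTCATGCAGCTAAGTTATTATTAATCTTTCTCCAGGTTGGCTACGCT
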