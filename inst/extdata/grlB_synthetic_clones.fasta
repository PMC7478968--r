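>grlB_B1
ATACCATCGATCAGGGAATCCCTAGGCCAGCGGATATCACGGTACCTGAACGATTGCACCGTTCGGCAAAATAGGGGCTCCCCTTATCTTAGGTTTAGTAGCACGCTGATCCGCTCGATGAGCAAAAGACCGACGCAGTCCGCGCTTCATGCAGCTAAGTTATTATTAATCTTTCTCCAGGTTGGCTACGCT
>grlB_B2
ATACCATCGATCAGGGAATCCCTAGGCCAGCGGATATCACGGTACCTGAACGATTGCACATAATAGGGGCTCCCCTTATCTTAGGTTTAGTAGCACGCTGATCCGCTCGATGAGCAAAAGACCGACGCAGTCCGCGCTTCATGCAGCTAAGTTATTATTAATCTTTCTCCAGGTTGGCTACGCT
>grlB_B4
ATACCATCGATCAGGGAATCCCTAGGCCAGCGGATATCACGGTACCTGAACGATTTAGGGGCTCCCCTTATCTTAGGTTTAGTAGCACGCTGATCCGCTCGATGAGCAAAAGACCGACGCAGTCCGCGCTTCATGCAGCTAAGTTATTATTAATCTTTCTCCAGGTTGGCTACGCT
>grlB_B9
ATACCATCGATCAGGGAATCCCTAGGCCAGCGGATATCACGGTACCCCCTTATCTTAGGTTTAGTAGCACGCTGATCCGCTCGATGAGCAAAAGACCGACGCAGTCCGCGCTTCATGCAGCTAAGTTATTATTAATCTTTCTCCAGGTTGGCTACGCT
>grlB_B10
ATACCATCGATCAGGGAATCCCTAGGCCAGCGGATATCACGGTACCTGAACGATTGCATTAATAGGGGCTCCCCTTATCTTAGGTTTAGTAGCACGCTGATCCGCTCGATGAGCAAAAGACCGACGCAGTCCGCGCTTCATGCAGCTAAGTTATTATTAATCTTTCTCCAGGTTGGCTACGCT
>grlB_B12
ATACCATCGATCAGGGAATCCCTAGGCCAGCGGATATCACGGTACCTGAACGATTGCGCTGCAAAATAGGTGCTCCCCTTATCTTAGGTTTAGTAGCACGCTGATCCGCTCGATGAGCAAAAGACCGACGCAGTCCGCGCTTCATGCAGCTAAGTTATTATTAATCTTTCTCCAGGTTGGCTACGCT
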