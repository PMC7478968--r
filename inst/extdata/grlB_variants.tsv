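clone_id	kind	position	ref_allele	alt_allele	status
grlB_B1	insertion	57		ACCGTTCGGCAA	ok
grlB_B2	insertion	57		ACAT	ok
grlB_B3	none	NA			failed_sequencing
grlB_B4	deletion	55	GCAA		ok
grlB_B5	none	NA			failed_sequencing
grlB_B6	none	NA			failed_sequencing
grlB_B7	none	NA			failed_sequencing
grlB_B8	none	NA			failed_sequencing
grlB_B9	deletion	45	CTGAACGATTGCAATAGGGGCT		ok
grlB_B10	insertion	57		ATT	ok
grlB_B11	none	NA			failed_sequencing
grlB_B12	insertion	57		GCTGCAA	ok
grlB_B12	substitution	63	G	T	ok
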