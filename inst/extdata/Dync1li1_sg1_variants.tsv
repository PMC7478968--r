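clone_id	kind	position	ref_allele	alt_allele	status
Dyn1_N1	none	NA			ok
Dyn1_N2	none	NA			ok
Dyn1_N3	none	NA			ok
Dyn1_N4	none	NA			ok
Dyn1_N5	substitution	57	A	T	ok
Dyn1_N6	substitution	56	CA	TT	ok
Dyn1_N7	insertion	57		CCG	ok
Dyn1_N8	deletion	47	GAACGATTGCAATAGGGGCTC		ok
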