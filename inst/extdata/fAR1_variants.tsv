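clone_id	kind	position	ref_allele	alt_allele	status
fAR1_N1	deletion	56	CAA		ok
fAR1_N2	deletion	57	A		ok
fAR1_N3	insertion	57		G	ok
fAR1_N4	deletion	56	CA		ok
fAR1_N5	insertion	57		CA	ok
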