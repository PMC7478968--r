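clone_id	kind	position	ref_allele	alt_allele	status
grlC_C1	insertion	57		AT	ok
grlC_C1	substitution	62	G	A	ok
grlC_C2	insertion	57		AT	ok
grlC_C2	substitution	62	G	A	ok
grlC_C3	deletion	57	A		ok
grlC_C4	deletion	54	TGCAAT		ok
grlC_C5	insertion	57		TAC	ok
grlC_C5	substitution	61	G	A	ok
grlC_C6	deletion	52	A		ok
grlC_C7	deletion	48	AACGATTGCAATAGGGG		ok
grlC_C8	insertion	57		TTAG	ok
grlC_C8	substitution	50	C	T	ok
grlC_C8	substitution	62	G	T	ok
grlC_C8	substitution	64	G	T	ok
grlC_C9	insertion	57		GG	ok
grlC_C9	substitution	61	G	C	ok
grlC_C9	substitution	63	G	T	ok
grlC_C10	deletion	56	CAA		ok
grlC_C11	deletion	52	A		ok
grlC_C12	insertion	57		TA	ok
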