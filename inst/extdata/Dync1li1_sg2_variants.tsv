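clone_id	kind	position	ref_allele	alt_allele	status
Dyn2_N1	none	NA			ok
Dyn2_N2	none	NA			ok
Dyn2_N3	none	NA			ok
Dyn2_N4	substitution	57	A	C	ok
Dyn2_N5	substitution	58	A	G	ok
Dyn2_N6	deletion	54	TGCAAT		ok
Dyn2_N7	deletion	52	ATTGCAATA		ok
Dyn2_N8	deletion	55	GCA		ok
Dyn2_N9	deletion	56	CAA		ok
Dyn2_N10	deletion	57	AAT		ok
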