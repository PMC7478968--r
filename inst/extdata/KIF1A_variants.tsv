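clone_id	kind	position	ref_allele	alt_allele	status
KIF1A_N01	none	NA			ok
KIF1A_N02	none	NA			ok
KIF1A_N03	deletion	50	CGATT		ok
KIF1A_N04	deletion	51	GATTG		ok
KIF1A_N05	deletion	52	ATTGC		ok
KIF1A_N06	deletion	53	TTGCA		ok
KIF1A_N07	deletion	54	TGCAA		ok
KIF1A_N08	deletion	55	GCAAT		ok
KIF1A_N09	deletion	56	CAATA		ok
KIF1A_N10	deletion	53	TTGCAA		ok
KIF1A_N11	deletion	52	ATT		ok
KIF1A_N12	deletion	53	TTG		ok
KIF1A_N13	deletion	54	TGC		ok
KIF1A_N14	deletion	55	GCA		ok
KIF1A_N15	deletion	56	CAA		ok
KIF1A_N16	insertion	57		GACTT	ok
KIF1A_N16	substitution	63	G	T	ok
KIF1A_N17	substitution	57	A	T	ok
KIF1A_N18	substitution	56	CA	TG	ok
KIF1A_N19	substitution	58	A	C	ok
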