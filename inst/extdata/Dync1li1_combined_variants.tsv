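clone_id	kind	position	ref_allele	alt_allele	status
DynC_N01	none	NA			ok
DynC_N02	none	NA			ok
DynC_N03	none	NA			ok
DynC_N04	deletion	53	TTG		ok
DynC_N05	deletion	54	TGC		ok
DynC_N06	deletion	55	GCA		ok
DynC_N07	deletion	56	CAA		ok
DynC_N08	deletion	57	AAT		ok
DynC_N09	deletion	50	CGATTG		ok
DynC_N10	deletion	52	ATTGCA		ok
DynC_N11	deletion	54	TGCAAT		ok
DynC_N12	deletion	48	AACGATTGC		ok
DynC_N13	deletion	51	GATTGCAAT		ok
DynC_N14	deletion	45	CTGAACGATTGCAATAGGGGC		ok
DynC_N15	insertion	57		TGC	ok
DynC_N16	insertion	57		TAA	ok
DynC_N17	insertion	56		GTA	ok
DynC_N18	substitution	55	G	C	ok
DynC_N19	substitution	56	CA	GG	ok
DynC_N20	substitution	57	A	T	ok
DynC_N21	substitution	58	ATA	GAT	ok
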