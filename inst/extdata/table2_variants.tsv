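sample_id	gene	dna_variant	dna_vaf	rna_variant	rna_vaf
BBIRE-T 2691	BRAF	D594N	37	D594N	61
BBIRE-T 2393	BRAF	L597S	61	L597S	65
BBIRE-T 1957	BRAF	V600E	83	V600E	31
BBIRE-T 2217	BRAF	V600E	na	V600E	72
BBIRE-T 1978	BRAF	V600E	20	V600E	68
BBIRE-T 2546	BRAF	V600E	34	V600E	38
BBIRE-T 1848	BRAF	V600E	28	V600E	30
BBIRE-T 1918	BRAF	V600E	62	V600E	63
BBIRE-T 2482	BRAF	V600E	60	V600E	75
BBIRE-T 1841	BRAF	V600E	53	V600E	43
BBIRE-T 2615	BRAF	V600E	32	WT	-
BBIRE-T 2648	BRAF	V600E	47	V600E	70
BBIRE-T 1995	BRAF	V600K	72	V600K	87
BBIRE-T 2450	BRAF	V600K	34	V600K	55
BBIRE-T 2108	BRAF	V600E	37	V600E	50
BBIRE-T 2177	BRAF	V600E	25	V600E	46
BBIRE-T 2263	BRAF	V600K	na	V600K	67
BBIRE-T 1773	NRAS	G13D	16	G13D	80
BBIRE-T 2061	NRAS	Q61K	42	Q61K	59
BBIRE-T 2074	NRAS	Q61K	29	WT	-
BBIRE-T 2523	NRAS	Q61K	27	G13D	44
BBIRE-T 2569	NRAS	Q61L	43	G13D	42
BBIRE-T 2371	NRAS	Q61L	na	Q61L	54
BBIRE-T 1652	NRAS	Q61R	27	Q61R	33
BBIRE-T 2542	BRAF	V600E	na	WT	-
BBIRE-T 2658	-	WT	-	-	-
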