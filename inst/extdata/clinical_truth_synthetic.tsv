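sample	gene	scope	outcome	chrom	pos	ref	alt
1CB-a	BRCA2	full_screen	positive	chr13	32339966	AGTAA	-
1CAD-a	BRCA1	targeted	positive	chr17	43051071	A	C
1EA-a	BRCA1	full_screen	negative_full_screen	.	.	.	.
1EA-a	BRCA2	full_screen	negative_full_screen	.	.	.	.
1EAC-a	BRCA1	full_screen	negative_full_screen	.	.	.	.
1EAC-a	BRCA2	full_screen	negative_full_screen	.	.	.	.
1CD-a	BRCA1	full_screen	negative_full_screen	.	.	.	.
1CD-a	BRCA2	full_screen	negative_full_screen	.	.	.	.
3CC-a	BRCA1	full_screen	negative_full_screen	.	.	.	.
3CC-a	BRCA2	full_screen	negative_full_screen	.	.	.	.
4CA-a	BRCA1	full_screen	negative_full_screen	.	.	.	.
4CA-a	BRCA2	full_screen	negative_full_screen	.	.	.	.
1CF-a	BRCA1	full_screen	negative_full_screen	.	.	.	.
1CF-a	BRCA2	full_screen	negative_full_screen	.	.	.	.
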