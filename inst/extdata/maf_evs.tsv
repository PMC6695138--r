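chrom	pos	ref	alt	EA	AA
chr11	108227849	C	G	0.0136	0.0027
chr11	108229171	C	T	.	0.0142
chr11	108244860	C	T	0.0134	0.0023
chr11	108248927	T	G	0.0026	0.0002
chr11	108249096	T	C	0.0022	0.0009
chr11	108251973	T	C	0.0009	.
chr11	108253901	T	C	0.0006	.
chr11	108254034	T	C	0.0109	0.0039
chr11	108259051	C	A	0.0001	0.0198
chr11	108267276	T	C	0.012	0.0032
chr11	108284478	G	T	.	0.0098
chr11	108315883	G	A	0.0031	0.0007
chr11	108315904	A	G	.	0.0148
chr11	108317409	G	A	0.0006	0.0166
chr11	108327713	G	A	.	0.0014
chr17	43049113	A	G	.	0.0145
chr17	43051071	A	C	.	.
chr17	43070958	C	T	0.0152	0.002
chr17	43091492	T	C	0.0067	0.0011
chr17	43092362	T	C	.	.
chr17	43092509	T	C	.	0.0023
chr17	43093035	T	A	.	.
chr17	43093626	A	G	.	0.0005
chr17	43094408	G	T	.	.
chr17	43097280	G	T	.	0.0068
chr13	32332629	C	T	0.0015	0.0002
chr13	32332753	A	G	.	0.0098
chr13	32333266	T	C	0.0003	0.0163
chr13	32333276	T	C	.	0.0055
chr13	32333395	TG	-	0.0005	0.0059
chr13	32339375	A	G	.	.
chr13	32339554	C	T	0.0054	0.0009
chr13	32339966	AGTAA	-	.	.
chr13	32340678	G	A	0.0015	0.0068
chr13	32357750	G	A	.	0.0061
chr13	32363385	T	C	.	.
chr13	32371035	A	C	0.002	0.0005
chr16	68801830	A	G	0.0003	0.0061
chr16	68813324	G	T	.	.
chr16	68819394	G	C	0.0029	0.0007
chr22	28695232	A	G	0.0003	.
chr8	89955458	T	C	.	0.0082
chr8	89980833	A	G	0.0045	0.0018
chr8	89984520	C	T	0.001	0.0182
chr16	23629898	T	C	.	0.0055
chr16	23635127	T	G	.	0.0084
chr16	23635536	A	G	0.0197	0.0036
chr16	23638125	T	C	.	0.0155
chr10	87931070	C	T	.	0.0002
chr10	87960892	A	T	.	.
chr10	87960896	C	A	.	.
chr10	87960902	G	T	.	.
chr10	87960906	C	T	.	.
chr19	1218495	G	A	0.0002	0.0154
chr17	7670613	A	C	.	.
chr17	7673776	G	A	0.0002	.
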