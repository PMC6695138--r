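sample	chrom	pos	ref	alt	outcome
1CAI-a	chr11	108227849	C	G	confirmed
4CA-a	chr11	108229171	C	T	confirmed
1ED-a	chr11	108244860	C	T	confirmed
1CBE-a	chr11	108248927	T	G	confirmed
1EE-a	chr11	108249096	T	C	confirmed
1EAD-a	chr11	108251973	T	C	confirmed
1EAC-a	chr11	108253901	T	C	confirmed
1CBC-a	chr11	108254034	T	C	confirmed
1EBA-a	chr11	108259051	C	A	confirmed
1EAJ-a	chr11	108267276	T	C	confirmed
1CAD-f	chr11	108284478	G	T	confirmed
1CG-a	chr11	108315883	G	A	confirmed
1CAF-a	chr11	108315904	A	G	confirmed
1EA-a	chr11	108317409	G	A	confirmed
1CAC-a	chr11	108327713	G	A	confirmed
3CC-a	chr17	43049113	A	G	confirmed
4CA-a	chr17	43049113	A	G	confirmed
1CAD-a	chr17	43051071	A	C	confirmed
1EA-a	chr17	43070958	C	T	confirmed
1EAC-a	chr17	43091492	T	C	confirmed
1CE-a	chr17	43092362	T	C	confirmed
1EAG-a	chr17	43092509	T	C	confirmed
1CD-a	chr17	43093035	T	A	confirmed
1CF-a	chr17	43093626	A	G	confirmed
1CG-a	chr17	43094408	G	T	not_confirmed
3CC-a	chr17	43097280	G	T	confirmed
4CA-a	chr17	43097280	G	T	confirmed
1CD-a	chr13	32332629	C	T	confirmed
1CAI-a	chr13	32332753	A	G	confirmed
1CCB-a	chr13	32333266	T	C	confirmed
1EB-a	chr13	32333266	T	C	confirmed
1CAG-a	chr13	32333276	T	C	confirmed
1CAG-a	chr13	32333395	TG	-	confirmed
1CAD-a	chr13	32339375	A	G	confirmed
1CAD-f	chr13	32339375	A	G	confirmed
1CBE-a	chr13	32339554	C	T	confirmed
1CB-a	chr13	32339966	AGTAA	-	confirmed
1CAH-a	chr13	32340678	G	A	confirmed
1EAH-a	chr13	32357750	G	A	confirmed
1CAD-f	chr13	32363385	T	C	confirmed
1CAB-a	chr13	32371035	A	C	confirmed
1CAF-a	chr16	68801830	A	G	confirmed
1CBH-a	chr16	68801830	A	G	confirmed
1EE-a	chr16	68813324	G	T	not_confirmed
1CAI-a	chr16	68819394	G	C	confirmed
1EA-a	chr22	28695232	A	G	confirmed
1CC-a	chr8	89955458	T	C	confirmed
1EAJ-a	chr8	89980833	A	G	confirmed
1CAH-a	chr8	89984520	C	T	confirmed
1CC-a	chr8	89984520	C	T	confirmed
1CCB-a	chr16	23629898	T	C	confirmed
1CAI-a	chr16	23635127	T	G	confirmed
1EG-a	chr16	23635536	A	G	confirmed
1CC-a	chr16	23638125	T	C	confirmed
1EAG-a	chr16	23638125	T	C	confirmed
1CA-a	chr10	87931070	C	T	confirmed
1CAF-a	chr10	87960892	A	T	not_confirmed
1CD-a	chr10	87960892	A	T	not_confirmed
1CF-a	chr10	87960892	A	T	not_confirmed
1EAJ-a	chr10	87960892	A	T	not_confirmed
1CC-a	chr10	87960896	C	A	not_confirmed
1EE-a	chr10	87960896	C	A	not_confirmed
3CC-a	chr10	87960896	C	A	not_confirmed
1CAB-a	chr10	87960902	G	T	not_confirmed
1CAF-a	chr10	87960902	G	T	not_confirmed
1CC-a	chr10	87960902	G	T	not_confirmed
1CC-a	chr10	87960906	C	T	not_confirmed
1CAG-a	chr19	1218495	G	A	confirmed
1CBH-a	chr19	1218495	G	A	confirmed
1CE-a	chr19	1218495	G	A	confirmed
1EBA-a	chr19	1218495	G	A	confirmed
1EB-a	chr19	1218495	G	A	confirmed
1EBA-a	chr17	7670613	A	C	confirmed
1EC-a	chr17	7673776	G	A	confirmed
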