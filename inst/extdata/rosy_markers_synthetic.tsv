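position	kind	footprint	allele_p1	allele_p2	is_selection_site	mutant_parent	bounds_lo	bounds_hi
-5950	snp	1	T	C	FALSE		-6150	9300
-950	snp	1	A	G	FALSE		-6150	9300
-800	snp	1	C	T	FALSE		-6150	9300
-720	snp	1	G	A	FALSE		-6150	9300
-706	snp	1	T	C	FALSE		-6150	9300
-600	indel	2	CAT	C	FALSE		-6150	9300
-468	snp	1	C	T	TRUE	P2	-6150	9300
-455	snp	1	G	A	FALSE		-6150	9300
-310	snp	1	T	C	FALSE		-6150	9300
-302	snp	1	A	G	FALSE		-6150	9300
-150	snp	1	C	T	FALSE		-6150	9300
20	snp	1	G	A	FALSE		-6150	9300
180	snp	1	T	C	FALSE		-6150	9300
195	snp	1	A	G	FALSE		-6150	9300
420	snp	1	C	T	FALSE		-6150	9300
700	snp	1	G	A	FALSE		-6150	9300
710	snp	1	T	C	FALSE		-6150	9300
980	snp	1	A	G	FALSE		-6150	9300
1300	snp	1	C	T	FALSE		-6150	9300
1620	snp	1	G	A	FALSE		-6150	9300
1900	snp	1	T	C	FALSE		-6150	9300
2150	snp	1	A	G	FALSE		-6150	9300
2160	snp	1	C	T	FALSE		-6150	9300
2400	snp	1	G	A	FALSE		-6150	9300
2700	indel	4	G	GTTAA	FALSE		-6150	9300
3000	snp	1	A	G	FALSE		-6150	9300
3150	snp	1	C	T	FALSE		-6150	9300
3312	snp	1	G	A	TRUE	P1	-6150	9300
3460	snp	1	T	C	FALSE		-6150	9300
3700	snp	1	A	G	FALSE		-6150	9300
4100	snp	1	C	T	FALSE		-6150	9300
9100	snp	1	A	G	FALSE		-6150	9300
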