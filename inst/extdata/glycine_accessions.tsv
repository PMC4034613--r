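accession	species	ploidy	progenitor1	progenitor2
1232	canescens	diploid
1126	clandestina	diploid
1253	clandestina	diploid
1134	T2	allopolyploid	D3	D4
1188	T2	allopolyploid	D3	D4
1286	T2	allopolyploid	D3	D4
1393	T2	allopolyploid	D3	D4
1854	T2	allopolyploid	D3	D4
1300	D4	diploid
2073	D4	diploid
2321	D4	diploid
1156	D1	diploid
1157	D1	diploid
1316	D1	diploid
1364	D3	diploid
1366	D3	diploid
1403	D3	diploid
1820	D3	diploid
1288	T1	allopolyploid	D1	D3
1361	T1	allopolyploid	D1	D3
1763	T1	allopolyploid	D1	D3
A58_1	T5	allopolyploid	A	D1
1487	T5	allopolyploid	A	D1
1969	T5	allopolyploid	A	D1
William82	Gmax	outgroup
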