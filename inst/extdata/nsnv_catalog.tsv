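position	rs	aa_change	ref	alt	codon_change	type	prot_effect	alig_freq	kgen_freq	gene	codon_position
146	rs370482130	-	T	C	-	Ts	-	28.4	21.4	-	-
150	rs62581312	-	C	T	-	Ts	-	20.9	19.1	-	-
152	rs117135796	-	T	C	-	Ts	-	38.8	33	-	-
185	rs879015046	-	G	A	-	Ts	-	4.5	3.7	-	-
189	rs371543232	-	A	G	-	Ts	-	19.4	7.7	-	-
195	rs2857291	-	T	C	-	Ts	-	13.4	24.7	-	-
247	rs41334645	-	G	A	-	Ts	-	17.9	7	-	-
709	rs2853517	-	G	A	-	Ts	-	26.9	16.7	-	-
769	rs2853519	-	G	A	-	Ts	-	22.4	16.4	-	-
825	rs2853520	-	T	A	-	Tv	-	17.9	7.1	-	-
827	rs28358569	-	A	G	-	Ts	-	16.4	4.3	-	-
1018	rs2856982	-	G	A	-	Ts	-	22.4	16.5	-	-
2706	rs2854128	-	A	G	-	Ts	-	80.6	89	-	-
2758	rs2856980	-	G	A	-	Ts	-	6	6.6	-	-
2885	rs2854130	-	T	C	-	Ts	-	16.4	6.8	-	-
3010	rs3928306	-	G	A	-	Ts	-	17.9	11.2	-	-
3594	rs193303025	-	C	T	GTC>GTT	Ts	No change	20.9	15.9	ND1	3
4104	rs1117205	-	A	G	CTA>CTG	Ts	No change	19.4	15.8	ND1	3
4312	rs193303033	-	C	T	-	Ts	-	14.9	1.8	tRNA	-
4688	rs878853056	-	T	C	GCT>GCC	Ts	No change	4.5	0.4	ND2	3
5460	rs3021088	A>T	G	A	GCC>ACC	Ts	AA change	19.4	7.5	ND2	1
5471	rs879108598	-	G	A	ACG>ACA	Ts	No change	16.4	0.5	ND2	3
5821	rs56133209	-	G	A	-	Ts	-	14.9	0.5	tRNA	-
6962	rs1970771	-	G	A	CTG>CTA	Ts	No change	3	3	COX1	3
7146	rs372136420	T>A	A	G	ACT>GCT	Ts	AA change	6	6.1	COX1	1
7256	-	-	C	T	AAC>AAT	Ts	No change	20.9	15.8	COX1	3
7424	-	-	A	G	GAA>GAG	Ts	No change	16.4	2.3	COX1	3
7521	rs199474817	-	G	A	-	Ts	-	20.9	16	tRNA	-
7650	-	T>I	C	T	ACC>ATC	Ts	AA change	13.4	0	COX2	2
8386	-	-	C	T	ACC>ACT	Ts	No change	14.9	0	ATP8	3
8468	rs1116907	-	C	T	CTA>TTA	Ts	No change	16.4	6.7	ATP8	1
8655	-	-	C	T	ATC>ATT	Ts	No change	17.9	7.1	ATP6	3
9053	rs199646902	S>N	G	A	AGC>AAC	Ts	AA change	14.9	2.6	ATP6	2
9090	rs386829064	-	T	C	TCT>TCC	Ts	No change	3	0.3	ATP6	3
9755	rs2856985	-	G	A	GAG>GAA	Ts	No change	14.9	2	COX3	3
10310	rs41467651	-	G	A	CTG>CTA	Ts	No change	16.4	4	ND3	3
10373	rs28358277	-	G	A	GAG>GAA	Ts	No change	14.9	3	ND3	3
10586	rs28358281	-	G	A	TCG>TCA	Ts	No change	3	2.6	ND4L	3
10664	-	-	C	T	GTC>GTT	Ts	No change	14.9	1.8	ND4L	3
10688	rs2853488	-	G	A	GTG>GTA	Ts	No change	17.9	7	ND4L	3
10810	rs28358282	-	T	C	CTT>CTC	Ts	No change	17.9	7.1	ND4	3
10915	rs2857285	-	T	C	TGT>TGC	Ts	No change	14.9	2.3	ND4	3
11914	rs2853496	-	G	A	ACG>ACA	Ts	No change	23.9	12.7	ND4	3
12366	-	-	A	G	CTA>CTG	Ts	No change	14.9	0.2	ND5	3
12810	rs28359174	-	A	G	TGA>TGG	Ts	No change	4.5	2.4	ND5	3
13105	rs2853501	I>V	A	G	ATC>GTC	Ts	AA change	20.9	13.7	ND5	1
13276	rs2853502	M>V	A	G	ATA>GTA	Ts	AA change	14.9	1.8	ND5	1
14178	rs28357671	I>V	T	C	ATT>GTT	Ts	AA change	16.4	5.2	ND6	1
14560	rs28357676	-	G	A	GTC>GTT	Ts	No change	16.4	5.4	ND6	3
15148	rs527236206	-	G	A	CCG>CCA	Ts	No change	16.4	1.1	CYTB	3
15244	rs28357369	-	A	G	GGA>GGG	Ts	No change	4.5	2.1	CYTB	3
15355	rs527236181	-	G	A	ACG>ACA	Ts	No change	16.4	0.6	CYTB	3
16086	rs386420030	-	T	C	-	Ts	-	4.5	2.1	-	-
16093	rs2853511	-	T	C	-	Ts	-	13.4	5.6	-	-
16148	rs201893071	-	C	T	-	Ts	-	17.9	3.1	-	-
16169	rs879121566	-	C	T	-	Ts	-	1.5	0.8	-	-
16182	rs879044186	-	A	C	-	Tv	-	15.2	2.7	-	-
16183	rs28671493	-	A	G	-	Ts	-	1.5	0.4	-	-
16209	rs386829278	-	T	C	-	Ts	-	17.9	3	-	-
16230	rs2853514	-	A	G	-	Ts	-	14.9	2.1	-	-
16234	rs368259300	-	T	C	-	Ts	-	16.4	1.9	-	-
16278	rs41458645	-	C	T	-	Ts	-	25.4	20.8	-	-
16298	rs148377232	-	T	C	-	Ts	-	11.9	5	-	-
16311	rs34799580	-	T	C	-	Ts	-	34.3	18.7	-	-
16320	rs62581338	-	C	T	-	Ts	-	16.4	5.2	-	-
16519	rs3937033	-	T	C	-	Ts	-	61.2	62.3	-	-
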