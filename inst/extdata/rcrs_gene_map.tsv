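name	start	end	strand	kind
D-loop	16024	16569	H	CONTROL
D-loop	1	576	H	CONTROL
tRNA-Phe	577	647	H	TRNA
12S rRNA	648	1601	H	RRNA
tRNA-Val	1602	1670	H	TRNA
16S rRNA	1671	3229	H	RRNA
tRNA-Leu(UUR)	3230	3304	H	TRNA
ND1	3307	4262	H	PROTEIN
tRNA-Ile	4263	4331	H	TRNA
tRNA-Gln	4329	4400	L	TRNA
tRNA-Met	4402	4469	H	TRNA
ND2	4470	5511	H	PROTEIN
tRNA-Trp	5512	5579	H	TRNA
tRNA-Ala	5587	5655	L	TRNA
tRNA-Asn	5657	5729	L	TRNA
tRNA-Cys	5761	5826	L	TRNA
tRNA-Tyr	5826	5891	L	TRNA
COX1	5904	7445	H	PROTEIN
tRNA-Ser(UCN)	7446	7514	L	TRNA
tRNA-Asp	7518	7585	H	TRNA
COX2	7586	8269	H	PROTEIN
tRNA-Lys	8295	8364	H	TRNA
ATP8	8366	8572	H	PROTEIN
ATP6	8527	9207	H	PROTEIN
COX3	9207	9990	H	PROTEIN
tRNA-Gly	9991	10058	H	TRNA
ND3	10059	10404	H	PROTEIN
tRNA-Arg	10405	10469	H	TRNA
ND4L	10470	10766	H	PROTEIN
ND4	10760	12137	H	PROTEIN
tRNA-His	12138	12206	H	TRNA
tRNA-Ser(AGY)	12207	12265	H	TRNA
tRNA-Leu(CUN)	12266	12336	H	TRNA
ND5	12337	14148	H	PROTEIN
ND6	14149	14673	L	PROTEIN
tRNA-Glu	14674	14742	L	TRNA
CYTB	14747	15887	H	PROTEIN
tRNA-Thr	15888	15953	H	TRNA
tRNA-Pro	15956	16023	L	TRNA
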