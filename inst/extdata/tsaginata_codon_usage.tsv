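amino_acid	codon	count	rscu_published
Phe	UUU	99671	0.97
Phe	UUC	106107	1.03
Leu	UUA	38856	0.45
Leu	UUG	97522	1.13
Leu	CUU	107259	1.24
Leu	CUC	119595	1.38
Leu	CUA	52511	0.61
Leu	CUG	103594	1.20
Ile	AUU	109448	1.30
Ile	AUC	96607	1.15
Ile	AUA	47039	0.56
Met	AUG	113948	1.00
Val	GUU	95565	1.12
Val	GUC	85970	1.00
Val	GUA	45908	0.54
Val	GUG	115101	1.34
Ser	UCU	89398	1.11
Ser	UCC	97503	1.21
Ser	UCA	82438	1.02
Ser	UCG	72259	0.90
Ser	AGU	76215	0.94
Ser	AGC	66542	0.82
Pro	CCU	85183	1.10
Pro	CCC	79819	1.03
Pro	CCA	88760	1.14
Pro	CCG	56540	0.73
Thr	ACU	88533	1.13
Thr	ACC	89404	1.14
Thr	ACA	77048	0.98
Thr	ACG	58709	0.75
Ala	GCU	122134	1.21
Ala	GCC	111542	1.11
Ala	GCA	95661	0.95
Ala	GCG	73950	0.73
Tyr	UAU	55514	0.81
Tyr	UAC	81868	1.19
His	CAU	62791	0.95
His	CAC	68855	1.05
Gln	CAA	102281	0.96
Gln	CAG	110043	1.04
Asn	AAU	111522	1.07
Asn	AAC	97493	0.93
Lys	AAA	115265	0.92
Lys	AAG	135856	1.08
Asp	GAU	147181	1.10
Asp	GAC	120957	0.90
Glu	GAA	152714	0.91
Glu	GAG	181548	1.09
Cys	UGU	55868	0.99
Cys	UGC	57522	1.01
Arg	CGU	74482	1.33
Arg	CGC	67662	1.20
Arg	CGA	67187	1.20
Arg	CGG	41070	0.73
Arg	AGA	44857	0.80
Arg	AGG	41815	0.74
Gly	GGU	108511	1.38
Gly	GGC	86502	1.10
Gly	GGA	76898	0.98
Gly	GGG	41741	0.53
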