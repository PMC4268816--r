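amino_acid	codon	rscu_high	count_high	rscu_low	count_low	starred
Phe	UUU	0.69	2341	1.23	3032	0
Phe	UUC	1.31	4441	0.77	1907	1
Leu	UUA	0.20	540	0.90	1844	0
Leu	UUG	0.96	2598	1.35	2759	0
Leu	CUU	0.95	2570	1.34	2750	0
Leu	CUC	1.97	5332	0.79	1628	1
Leu	CUA	0.41	1099	0.74	1516	0
Leu	CUG	1.52	4118	0.88	1804	1
Ile	AUU	1.02	2797	1.43	3065	0
Ile	AUC	1.61	4442	0.78	1677	1
Ile	AUA	0.37	1025	0.79	1702	0
Met	AUG	1.00	4032	1.00	3118	0
Val	GUU	0.67	1925	1.40	2912	0
Val	GUC	1.14	3248	0.79	1635	1
Val	GUA	0.37	1061	0.77	1598	0
Val	GUG	1.82	5203	1.05	2177	1
Tyr	UAU	0.50	1151	1.13	1851	0
Tyr	UAC	1.50	3424	0.87	1414	1
His	CAU	0.65	1279	1.23	1936	0
His	CAC	1.35	2642	0.77	1216	1
Gln	CAA	0.71	2117	1.18	3336	0
Gln	CAG	1.29	3842	0.82	2309	1
Asn	AAU	0.79	2261	1.28	3935	0
Asn	AAC	1.21	3495	0.72	2199	1
Lys	AAA	0.62	2293	1.10	4690	0
Lys	AAG	1.38	5114	0.90	3805	1
Asp	GAU	0.87	3333	1.24	4539	0
Asp	GAC	1.13	4308	0.76	2767	1
Glu	GAA	0.56	2716	1.13	6131	0
Glu	GAG	1.44	6946	0.87	4759	1
Ser	UCU	0.80	1672	1.26	2823	0
Ser	UCC	1.51	3157	0.87	1951	1
Ser	UCA	0.74	1540	1.32	2967	0
Ser	UCG	1.06	2216	0.79	1772	1
Ser	AGU	0.85	1770	1.03	2318	0
Ser	AGC	1.03	2150	0.73	1640	1
Pro	CCU	0.91	1919	1.21	2292	0
Pro	CCC	1.32	2776	0.74	1399	1
Pro	CCA	0.89	1875	1.45	2734	0
Pro	CCG	0.87	1821	0.60	1139	0
Thr	ACU	0.96	2294	1.21	2521	0
Thr	ACC	1.49	3545	0.83	1731	1
Thr	ACA	0.70	1678	1.25	2607	0
Thr	ACG	0.85	2015	0.71	1486	0
Ala	GCU	1.00	3271	1.31	3013	0
Ala	GCC	1.38	4515	0.80	1840	1
Ala	GCA	0.71	2315	1.28	2935	0
Ala	GCG	0.92	3009	0.62	1417	1
Cys	UGU	0.79	1441	1.08	1673	0
Cys	UGC	1.21	2188	0.92	1416	1
Trp	UGG	1.00	2015	1.00	1293	0
Arg	CGU	1.60	2637	0.93	1267	1
Arg	CGC	1.88	3105	0.61	830	1
Arg	CGA	0.99	1639	1.03	1414	0
Arg	CGG	0.71	1176	0.63	858	0
Arg	AGA	0.34	567	1.62	2220	0
Arg	AGG	0.48	795	1.18	1612	0
Gly	GGU	1.40	3673	1.18	2195	1
Gly	GGC	1.46	3819	0.80	1487	1
Gly	GGA	0.66	1742	1.39	2572	0
Gly	GGG	0.48	1252	0.62	1158	0
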