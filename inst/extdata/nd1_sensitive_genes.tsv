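rank	locus_tag	product	L	K	E	P
1	60124	Protein of unknown function	1980	38	15.66	1.11e-6
2	50240	Conserved protein of unknown function	3540	44	22.66	4.30e-5
3	50464	FumC: fumarate hydratase (fumarase C), aerobic class II	1455	29	12.96	7.75e-5
4	62020	Conserved protein of unknown function	3270	43	23.02	1.20e-4
5	60419	IspU: undecaprenyl pyrophosphate synthase	786	16	5.99	4.71e-4
6	63509	Conserved protein of unknown function	5319	53	32.37	5.16e-4
7	50535	Sensory response regulator with diguanylate cyclase domain	2127	32	16.78	5.75e-4
8	61480	Conserved protein of unknown function	2316	37	20.91	8.77e-4
9	63396	YaeT: putative outer membrane protein assembly factor	2325	36	20.29	9.74e-4
10	62925	Sigma-54 dependent transcriptional regulator (Modular protein)	2601	33	18.10	1.00e-3
11	61386	TonB-dependent siderophore receptor	2334	34	19.27	1.45e-3
12	62179	Conserved exported protein of unknown function	507	11	3.69	1.45e-3
13	50325	FlgG: flagellar component of cell-distal portion of basal-body rod	792	16	6.71	1.50e-3
14	50347	Protein of unknown function	5361	59	38.96	1.59e-3
15	63512	Conserved protein of unknown function	3252	31	17.19	1.67e-3
16	60586	Exported protein of unknown function	1371	23	11.52	1.77e-3
17	61395	Putative TonB-dependent receptor	2262	35	20.30	1.80e-3
18	60858	ThiI: putative tRNA sulfurtransferase	1179	21	10.20	1.90e-3
19	50308	FlgE: flagellar hook protein	1224	22	10.98	2.09e-3
20	61921	Putative regulatory protein, MerR family, cobalamin B12-binding	918	16	6.9	2.10e-3
21	63111	Efflux transporter, outer membrane factor lipoprotein	1521	23	11.69	2.12e-3
22	63116	HyfR: hydrogenase-4 transcriptional activator	2043	29	16.12	2.33e-3
23	62910	Putative di-haem cytochrome c	2076	28	15.46	2.50e-3
24	63252	RhlE: ATP-dependent RNA helicase	1353	18	8.49	2.86e-3
25	61398	Putative TonB-dependent receptor	2325	35	20.92	2.89e-3
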