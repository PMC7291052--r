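sequence	occurrence_in_substrates	v0	f_max	k
AACU	17	6.421	85.67	7.50e-2
AACG	24	5.669	84.23	6.73e-2
AAUU	12	5.652	84.36	6.70e-2
AAUG	21	0.998	74.66	1.34e-2
UACU	32	0.701	58.59	1.20e-2
UAUU	11	0.697	62.44	1.12e-2
AAUC	28	0.649	75.43	8.61e-3
AAUA	20	0.509	59.29	8.58e-3
AACA	21	0.427	53.82	7.93e-3
CAUU	20	0.423	53.20	7.95e-3
GACU	15	0.421	65.96	6.38e-3
AACC	28	0.410	49.96	8.21e-3
CACU	17	0.398	58.92	6.75e-3
GAUU	24	0.390	63.03	6.19e-3
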