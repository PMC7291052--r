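name	sequence
DR-14-AAUU	aaaaaAAUUaaaaa
DR-14-UAUU	aaaaaUAUUaaaaa
DR-14-GAUU	aaaaaGAUUaaaaa
DR-14-CAUU	aaaaaCAUUaaaaa
DR-14-AAUA	aaaaaAAUAaaaaa
DR-14-AAUG	aaaaaAAUGaaaaa
DR-14-AAUC	aaaaaAAUCaaaaa
DR-14-AACU	aaaaaAACUaaaaa
DR-14-UACU	aaaaaUACUaaaaa
DR-14-GACU	aaaaaGACUaaaaa
DR-14-CACU	aaaaaCACUaaaaa
DR-14-AACA	aaaaaAACAaaaaa
DR-14-AACG	aaaaaAACGaaaaa
DR-14-AACC	aaaaaAACCaaaaa
D-13-AAA	aaaaaaaaaaaaa
R-13-GUUGU	GUUGUCAUGCCGG
R-13-UCUCG	UCUCGGUGCGUUG
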