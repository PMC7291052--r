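locus_tag	product	L
50353	FlaG: flagellar protein	372
50758	Putative nucleotidyltransferase (fragment)	183
50957	Insertion element ISR1 uncharacterized 10 kDa protein A3 (fragment)	159
60210	TadA: tRNA-specific adenosine deaminase	489
60360	RcnA: putative nickel/cobalt efflux system	708
60698	AcyP: acylphosphatase	348
60976	Bfr: bacterioferritin, iron storage and detoxification protein	480
60984	MreD: putative cell shape-determining protein	501
61420	Nqo: NADH-quinone oxidoreductase chain 10	513
61675	MerT: mercuric transport protein	381
61748	Putative membrane protein insertion efficiency factor (modular protein)	264
62137	K+-transporting ATPase, F subunit (fragment)	90
62252	RbfA: ribosome-binding factor A	399
62630	Cytochrome bd-type quinol oxidase, subunit 2	1017
62661	AtpE: ATP synthase subunit c	231
62937	YitW: MIP18 family protein	324
63168	TatA: Sec-independent protein translocase protein	294
63277	Sulfate-binding protein (fragment)	492
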