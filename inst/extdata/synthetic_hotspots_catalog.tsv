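gene	contig	genomic_pos	ref	alt	alias
TERT	chr5	1295228	G	A	C228T (-124)
TERT	chr5	1295250	G	A	C250T (-146)
TP53	chr17	7577534	C	A	R249S
TP53	chr17	7577120	C	T	R273H
TP53	chr17	7578406	C	T	R175H
CTNNB1	chr3	41266101	C	T	S33F
CTNNB1	chr3	41266113	C	T	S37F
AXIN1	chr16	347209	G	A	R395Q
ARID1A	chr1	27100181	C	T	R1989X
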