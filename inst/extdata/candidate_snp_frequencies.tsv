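gene	snp	allele1	allele2	f_hom1	f_het	f_hom2	p1	hwe_flag	n
ALDH18A1	26:g.17130318C>A	A	C	0.6840	0.2868	0.0292	0.8274	T	924
ALDH18A1	26:g.17118244G>A	A	G	0.0195	0.2089	0.7716	0.1239	T	924
ALDH18A1	26:g.17102977T>C	C	T	0.0216	0.2089	0.7695	0.1261	T	924
ALDH18A1	26:g.17100534G>T	G	T	0.8680	0.1288	0.0032	0.9324	T	924
ALDH18A1	26:g.17089560G>A	A	G	0.0119	0.1656	0.8225	0.0947	T	924
ALDH18A1	26:g.17088978A>G	A	G	0.0606	0.3312	0.6082	0.2262	T	924
ALDH18A1	26:g.17088098G>C	C	G	0.3506	0.4610	0.1883	0.5812	T	924
ALDH18A1	26:g.17086802T>A	A	T	0.3712	0.4600	0.1688	0.6012	T	924
MAT2A	11:g.49472723G>C	C	G	0.6396	0.3214	0.0390	0.8003	T	924
MAT2A	11:g.49465032C>T	C	T	0.4913	0.3798	0.1288	0.6813	F	924
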