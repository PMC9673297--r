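trait	qtl	chrom	ci_start	ci_end	lead_pos	allele0	allele1	maf	p
DFW	1	7	138910411	139598335	138975863	T	C	0.053963	1.36e-07
DFW	2	11	64944841	64952273	64951174	G	C	0.071669	7.12e-23
CVDFW	1	11	64270630	65432659	65412003	A	T	0.079723	1.42e-11
BW	1	2	8257045	8923024	8877739	G	A	0.174952	7.33e-12
BW	2	4	36704911	38161753	38127528	A	G	0.083174	5.93e-07
BW	3	12	148360582	148642693	148369145	G	A	0.083174	4.61e-07
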