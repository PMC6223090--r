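chrom	pos	ref	alt	site_id	outcome
chr1	101	C	T	siteA	poor_met
chr1	102	C	T	siteA	poor_met
chr1	103	G	A	siteB	poor_met
chr1	104	A	G	siteC	good
chr1	105	T	C	siteD	good
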