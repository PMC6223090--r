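chrom	pos	base	baseq	mapq	sample
chr1	101	C	30	30	s1
chr1	101	C	30	30	s1
chr1	101	C	30	30	s1
chr1	101	C	30	30	s1
chr1	101	C	30	30	s1
chr1	101	C	30	30	s1
chr1	101	C	30	30	s1
chr1	101	C	30	30	s1
chr1	101	C	30	30	s1
chr1	101	T	30	30	s1
chr1	101	T	30	30	s1
chr1	102	C	30	30	s1
chr1	102	C	30	30	s1
chr1	102	C	30	30	s1
chr1	102	C	30	30	s1
chr1	102	T	30	30	s1
chr1	102	T	30	30	s1
chr1	102	T	30	30	s1
chr1	102	T	30	30	s1
chr1	102	T	30	30	s1
chr1	103	G	30	30	s1
chr1	103	G	30	30	s1
chr1	103	G	30	30	s1
chr1	103	G	30	30	s1
chr1	103	G	30	30	s1
chr1	103	G	30	30	s1
chr1	103	G	30	30	s1
chr1	103	G	30	30	s1
chr1	103	G	30	30	s1
chr1	103	G	30	30	s1
chr1	103	G	30	30	s1
chr1	103	G	30	30	s1
chr1	104	A	30	30	s1
chr1	104	A	30	30	s1
chr1	104	A	30	30	s1
chr1	104	A	30	30	s1
chr1	104	A	30	30	s1
chr1	104	A	30	30	s1
chr1	104	A	30	30	s1
chr1	104	A	30	30	s1
chr1	104	A	30	30	s1
chr1	104	G	30	30	s1
chr1	104	G	5	30	s1
chr1	105	T	30	30	s1
chr1	105	T	30	30	s1
chr1	105	T	30	30	s1
chr1	105	T	30	30	s1
chr1	105	T	30	30	s1
chr1	105	T	30	30	s1
chr1	105	T	30	30	s1
chr1	105	T	30	30	s1
chr1	105	T	30	30	s1
chr1	105	T	30	30	s1
chr1	105	C	30	30	s1
chr1	105	*	30	30	s1
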