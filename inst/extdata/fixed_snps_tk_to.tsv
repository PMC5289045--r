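snp_no	pos_a	allele_a	pos_b	allele_b	annotation	mutation_type	coding_effect
1	199	T	199	A	Inter space between trnH-GUG and psbA	Transversion	-
2	10984	A	10984	C	Inter space between psbM and trnD-GUC	Transversion	-
3	19580	T	19579	C	rpoC2	Transition	Synonymous
4	22844	C	22843	A	rpoC2	Transversion	Synonymous
5	55885	T	55798	C	rbcL	Transition	Synonymous
6	56829	T	56742	C	Inter space between rbcL and accD	Transition	-
7	56954	A	56867	C	accD	Transversion	Synonymous
8	57823	C	57763	G	accD	Transversion	Non-synonymous
9	72351	T	72244	C	psi_psbT	Transition	Synonymous
10	73068	G	72961	T	psi_psbT	Transversion	Synonymous
11	80173	T	80067	G	rps8	Transversion	Synonymous
12	110014	G	109902	A	Inter space between trnN-GUU and rps15	Transition	-
13	113818	A	113727	C	ndhH	Transversion	Synonymous
14	115335	T	115244	C	ndhA	Transition	Non-synonymous
15	123069	T	122951	C	Inter space between trnL-UAG and rpl32	Transition	-
16	135299	C	135261	T	rrn16	Transition	-
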