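chrom	pos	ref	alt	qual	region_class	exonic_class	gene	aa_change	cadd_phred	maf_exac	sift	polyphen2_hdiv	polyphen2_hvar	lrt	mutation_taster	mutation_assessor	fathmm	metasvm	metalr	vest3	provean	ri	gerp	phastcons	phylop	rvis_esp	rvis_exac	rvis_local	pli	z_mis	mirsvr	gt_S1	dp_S1	gt_S2	dp_S2	gt_S3	dp_S3	is_indel
1	186355211	G	A	200	exonic	nonsynonymous_SNV	C1orf27	R109H	25.1	NA	0.01	0.96	0.9	D	D	M	-2.5	-1	0.3	0.6	-1	2	NA	NA	NA	0.5	0.7	0.3	0.01	-1.2	NA	hom_ref	31	het	30	het	28	FALSE
1	184792402	T	C	200	exonic	nonsynonymous_SNV	FAM129A	K295R	23.9	NA	0.02	0.98	0.93	D	D	M	-1.8	-0.7	0.25	0.65	-0.8	3	NA	NA	NA	0.8	0.4	0.6	0.05	-0.5	NA	hom_ref	31	het	30	het	28	FALSE
1	197128680	C	T	200	exonic	nonsynonymous_SNV	ZBTB41	D847N	23.1	NA	0.4	0.2	0.3	N	D	L	-2	-0.5	0.1	0.7	-1	3	NA	NA	NA	-0.2	0.4	-0.1	0.3	0.5	NA	hom_ref	31	het	30	het	28	FALSE
20	2776248	C	T	200	exonic	nonsynonymous_SNV	CPXM1	G573R	32	4e-04	0	0.99	0.97	D	D	M	1.2	-0.8	0.2	0.85	-4.6	7	5.3	1	7.6	-0.5	-0.3	0.2	0.95	1.8	NA	hom_ref	31	het	30	het	28	FALSE
11	74167200	AATAT	A	200	ncRNA	none	KCNE3	NA	3.11	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	hom_ref	31	het	30	het	28	TRUE
X	66765158	T	TGCAGCAGCA	200	exonic	nonframeshift_insertion	AR	NA	12.8	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	hom_ref	31	het	30	het	28	TRUE
17	26522009	T	TCACA	200	utr3	none	NLK	NA	1.7	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	hom_ref	31	het	30	het	28	TRUE
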