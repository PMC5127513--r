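metabolite	locus	snp	chrom	pos	effect_allele	other_allele	eaf	beta	beta_se	beta_p	or	or_l95	or_u95	or_p	n_cases	n_controls
isoleucine	PPM1K	rs7678928	4	89222827	T	C	0.46	0.09	0.013	5.6e-19	1.03	1.01	1.05	0.0055	25208	209575
isoleucine	GCKR	rs1260326	2	27730940	T	C	0.41	0.06	0.012	1.1e-09	0.94	0.92	0.96	3.9e-11	47877	267694
isoleucine	DDX19A	rs75950518	16	70378917	C	T	0.89	0.11	0.019	2.1e-08	1.05	1.01	1.10	0.016	13037	152713
isoleucine	TRMT61A	rs58101275	14	104008420	G	A	0.79	0.09	0.015	2.8e-08	1.04	1.01	1.08	0.012	13037	152713
isoleucine	CBLN1	rs1420601	16	49085649	C	T	0.40	0.07	0.013	3.7e-08	1.01	0.98	1.04	0.53	13037	152713
leucine	PPM1K	rs1440581	4	89226422	C	T	0.53	0.08	0.013	3.9e-25	1.04	1.02	1.07	0.00034	30169	215523
valine	PPM1K	rs1440581	4	89226422	C	T	0.53	0.10	0.013	4.4e-24	1.04	1.02	1.07	0.00034	30169	215523
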