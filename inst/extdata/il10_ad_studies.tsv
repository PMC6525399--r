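study_id	snp	resolution	control_xx	control_xy	control_yy	case_xx	case_xy	case_yy	ethnicity	country	control_source	hwe_p_reported
Arkwright2001	-1082A/G	genotype	16	21	13	22	30	16	Mixed	UK	population_based	0.27
Babic2016	-1082A/G	dominant_collapsed	25	107		9	28		Caucasian	Croatia	population_based	>0.05
Behniafard2018	-1082A/G	genotype	53	75	12	30	46	13	Asian	Iran	population_based	0.04
Behniafard2018	-819T/C	genotype	12	57	71	6	42	41	Asian	Iran	population_based	0.91
Behniafard2018	-592A/C	genotype	12	57	71	5	42	42	Asian	Iran	population_based	0.91
Bin2018	-1082A/G	genotype	36	159	16	30	53	21	Asian	Saudi Arabia	population_based	<0.05
Bin2018	-819T/C	genotype	21	102	88	14	54	36	Asian	Saudi Arabia	population_based	0.27
Bin2018	-592A/C	genotype	21	102	88	14	54	36	Asian	Saudi Arabia	population_based	0.27
Chang2006	-1082A/G	allele_only	344		28	174		14	Asian	China	population_based	>0.05
Chang2006	-819T/C	allele_only	250		122	132		56	Asian	China	population_based	>0.05
Chang2006	-592A/C	allele_only	250		122	132		56	Asian	China	population_based	>0.05
Esposito2015	-1082A/G	genotype	38	60	20	50	41	10	Caucasian	Italy	population_based	0.65
Esposito2015	-592A/C	genotype	6	39	73	13	49	42	Caucasian	Italy	population_based	0.79
Jain2017	-1082A/G	genotype	7	31	0	23	15	0	Asian	India	population_based	<0.05
Jain2017	-819T/C	genotype	1	28	9	8	26	4	Asian	India	population_based	<0.05
Jain2017	-592A/C	genotype	1	28	9	8	26	4	Asian	India	population_based	<0.05
Kayserova2012	-1082A/G	genotype	20	71	11	29	43	16	Caucasian	Czech Republic	population_based	<0.05
Kayserova2012	-819T/C	genotype	4	50	48	7	26	55	Caucasian	Czech Republic	population_based	0.04
Kayserova2012	-592A/C	genotype	5	48	49	8	25	55	Caucasian	Czech Republic	population_based	0.11
Lesiak2011	-1082A/G	genotype	67	89	48	54	75	34	Caucasian	Poland	population_based	0.09
Lesiak2014	-1082A/G	genotype	20	26	14	25	35	16	Caucasian	Poland	population_based	0.33
Reich2003	-1082A/G	genotype	49	118	47	18	53	23	Caucasian	Germany	population_based	0.13
Sheng2018	-819T/C	genotype	128	130	41	83	154	63	Asian	China	population_based	0.39
Sohn2007	-1082A/G	genotype	124	15	1	241	35	0	Asian	Korea	population_based	0.47
Sohn2007	-819T/C	genotype	66	68	6	145	104	27	Asian	Korea	population_based	0.02
Sohn2007	-592A/C	genotype	64	65	11	137	110	29	Asian	Korea	population_based	0.32
Stavric2012	-1082A/G	genotype	70	212	17	8	55	3	Caucasian	Macedonia	population_based	<0.05
Stavric2012	-819T/C	genotype	155	125	19	39	27	0	Caucasian	Macedonia	population_based	0.35
Stavric2012	-592A/C	genotype	28	117	154	3	27	36	Caucasian	Macedonia	population_based	0.40
Yinji2010	-1082A/G	genotype	109	20	0	143	30	0	Asian	China	population_based	0.34
Yinji2010	-819T/C	genotype	55	60	14	89	70	14	Asian	China	population_based	0.69
Yinji2010	-592A/C	genotype	55	60	14	89	70	14	Asian	China	population_based	0.69
Zakrzewski2010	-1082A/G	genotype	67	89	48	54	75	34	Caucasian	Poland	population_based	0.09
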