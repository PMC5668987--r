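sample_id	chrom	pos	gene_id	major_count	total_count	NM	MQ
S1	chrX	1000	G01	18	20	0	200
S1	chrX	1010	G01	25	30	1	210
S1	chrX	1020	G01	30	40	2	220
S1	chrX	1030	G01	45	50	3	230
S1	chrX	1040	G02	22	25	4	240
S1	chrX	1050	G02	55	60	5	250
S1	chrX	1060	G02	70	100	6	255
S2	chrX	1000	G01	21	21	0	190
S2	chrX	1010	G01	33	35	1	185
S2	chrX	1020	G01	28	28	2	176
S2	chrX	1030	G02	40	45	6	176
S2	chrX	1040	G02	26	30	3	200
S3	chrX	1000	G01	20	20	6	176
S3	chrX	1010	G01	50	64	0	254
S3	chrX	1020	G02	24	27	2	233
S1	chrX	2000	G03	30	40	7	200
S1	chrX	2010	G03	30	40	8	220
S2	chrX	2000	G03	25	30	9	255
S2	chrX	2010	G03	45	50	7	176
S3	chrX	2000	G03	33	40	10	240
S3	chrX	2010	G03	28	30	7	250
S1	chrX	3000	G04	30	40	0	175
S1	chrX	3010	G04	25	30	1	175
S2	chrX	3000	G04	22	25	2	100
S2	chrX	3010	G04	50	60	3	0
S3	chrX	3000	G04	35	40	4	150
S1	chrX	4000	G05	15	19	0	200
S2	chrX	4000	G05	10	15	1	210
S3	chrX	4000	G05	9	10	2	220
S3	chrX	4010	G05	4	5	3	230
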