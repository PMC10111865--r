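chrom	length	cen_start	cen_end	acrocentric	baseline_cn
chr1	248900000	121700000	125100000	0	2
chr2	242200000	91800000	96000000	0	2
chr3	198300000	87800000	94000000	0	2
chr4	190200000	48200000	51800000	0	2
chr5	181500000	46100000	50100000	0	2
chr6	170800000	58500000	62600000	0	2
chr7	159300000	58100000	62500000	0	2
chr8	145100000	43200000	47200000	0	2
chr9	138400000	42200000	45500000	0	2
chr10	133800000	38000000	41600000	0	2
chr11	135100000	51000000	55800000	0	2
chr12	133300000	34700000	38300000	0	2
chr13	114400000	16000000	18900000	1	2
chr14	107000000	16000000	18200000	1	2
chr15	102000000	17000000	20500000	1	2
chr16	90300000	36300000	38300000	0	2
chr17	83300000	22800000	27400000	0	2
chr18	80400000	15400000	21500000	0	2
chr19	58600000	24400000	28100000	0	2
chr20	64400000	26400000	30000000	0	2
chr21	46700000	10900000	13000000	1	2
chr22	50800000	13700000	17400000	1	2
chrX	156000000	58100000	63800000	0	2
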