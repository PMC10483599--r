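chr1	0	62500000	p12	gpos50
chr1	62500000	125000000	p11	acen
chr1	125000000	187125310	q11	acen
chr1	187125310	249250621	q12	gpos50
chr2	0	46650000	p12	gpos50
chr2	46650000	93300000	p11	acen
chr2	93300000	168249686	q11	acen
chr2	168249686	243199373	q12	gpos50
chr3	0	45500000	p12	gpos50
chr3	45500000	91000000	p11	acen
chr3	91000000	144511215	q11	acen
chr3	144511215	198022430	q12	gpos50
chr4	0	25200000	p12	gpos50
chr4	25200000	50400000	p11	acen
chr4	50400000	120777138	q11	acen
chr4	120777138	191154276	q12	gpos50
chr5	0	24200000	p12	gpos50
chr5	24200000	48400000	p11	acen
chr5	48400000	114657630	q11	acen
chr5	114657630	180915260	q12	gpos50
chr6	0	30500000	p12	gpos50
chr6	30500000	61000000	p11	acen
chr6	61000000	116057533	q11	acen
chr6	116057533	171115067	q12	gpos50
chr7	0	29950000	p12	gpos50
chr7	29950000	59900000	p11	acen
chr7	59900000	109519331	q11	acen
chr7	109519331	159138663	q12	gpos50
chr8	0	22800000	p12	gpos50
chr8	22800000	45600000	p11	acen
chr8	45600000	95982011	q11	acen
chr8	95982011	146364022	q12	gpos50
chr9	0	24500000	p12	gpos50
chr9	24500000	49000000	p11	acen
chr9	49000000	95106715	q11	acen
chr9	95106715	141213431	q12	gpos50
chr10	0	20100000	p12	gpos50
chr10	20100000	40200000	p11	acen
chr10	40200000	87867373	q11	acen
chr10	87867373	135534747	q12	gpos50
chr11	0	26850000	p12	gpos50
chr11	26850000	53700000	p11	acen
chr11	53700000	94353258	q11	acen
chr11	94353258	135006516	q12	gpos50
chr12	0	17900000	p12	gpos50
chr12	17900000	35800000	p11	acen
chr12	35800000	84825947	q11	acen
chr12	84825947	133851895	q12	gpos50
chr13	0	8950000	p12	gpos50
chr13	8950000	17900000	p11	acen
chr13	17900000	66534939	q11	acen
chr13	66534939	115169878	q12	gpos50
chr14	0	8800000	p12	gpos50
chr14	8800000	17600000	p11	acen
chr14	17600000	62474770	q11	acen
chr14	62474770	107349540	q12	gpos50
chr15	0	9500000	p12	gpos50
chr15	9500000	19000000	p11	acen
chr15	19000000	60765696	q11	acen
chr15	60765696	102531392	q12	gpos50
chr16	0	18300000	p12	gpos50
chr16	18300000	36600000	p11	acen
chr16	36600000	63477376	q11	acen
chr16	63477376	90354753	q12	gpos50
chr17	0	12000000	p12	gpos50
chr17	12000000	24000000	p11	acen
chr17	24000000	52597605	q11	acen
chr17	52597605	81195210	q12	gpos50
chr18	0	8600000	p12	gpos50
chr18	8600000	17200000	p11	acen
chr18	17200000	47638624	q11	acen
chr18	47638624	78077248	q12	gpos50
chr19	0	13250000	p12	gpos50
chr19	13250000	26500000	p11	acen
chr19	26500000	42814491	q11	acen
chr19	42814491	59128983	q12	gpos50
chr20	0	13750000	p12	gpos50
chr20	13750000	27500000	p11	acen
chr20	27500000	45262760	q11	acen
chr20	45262760	63025520	q12	gpos50
chr21	0	6600000	p12	gpos50
chr21	6600000	13200000	p11	acen
chr21	13200000	30664947	q11	acen
chr21	30664947	48129895	q12	gpos50
chr22	0	7350000	p12	gpos50
chr22	7350000	14700000	p11	acen
chr22	14700000	33002283	q11	acen
chr22	33002283	51304566	q12	gpos50
chrX	0	30300000	p12	gpos50
chrX	30300000	60600000	p11	acen
chrX	60600000	107935280	q11	acen
chrX	107935280	155270560	q12	gpos50
chrY	0	6250000	p12	gpos50
chrY	6250000	12500000	p11	acen
chrY	12500000	35936783	q11	acen
chrY	35936783	59373566	q12	gpos50
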