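##fileformat=VCFv4.2
##source=varbatch
##contig=<ID=1>
##INFO=<ID=VQSLOD,Number=1,Type=Float,Description="Recalibrated variant quality log-odds">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S001	S002	S003
1	1000	.	A	G	.	PASS	VQSLOD=4.25	GT:AD:DP:GQ	0/0:28,0:28:99	0/1:14,16:30:99	1/1:0,25:25:99
1	2000	.	C	T	.	PASS	VQSLOD=6.1	GT:AD:DP:GQ	0/1:11,9:20:95	./.:2,0:2:.	0/0:33,1:34:99
1	3000	.	G	GTT	.	PASS	VQSLOD=3.0	GT:AD:DP:GQ	0/0:20,0:20:99	0/0:22,0:22:99	0/1:9,8:17:88
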