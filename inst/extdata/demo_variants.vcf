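##fileformat=VCFv4.2
##INFO=<ID=DP,Number=1,Type=Integer,Description="Total depth">
##INFO=<ID=AF,Number=A,Type=Float,Description="Allele frequency">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	pool
contig_1	16	.	G	A	.	PASS	DP=150;AF=0.5	GT:AD	0/1:75,75
contig_2	50	.	A	G	.	PASS	.	GT:AD	0/1:50,49
contig_2	200	.	C	T	.	PASS	DP=150;AF=0.15	GT:AD	0/1:128,22
contig_2	300	.	AT	A	.	PASS	DP=140;AF=0.4	GT:AD	0/1:84,56
contig_2	320	.	G	C	.	PASS	DP=140;AF=0.45	GT:AD	0/1:77,63
contig_3	60	.	T	A	.	PASS	DP=120;AF=0.5	GT:AD	0/1:60,60
contig_3	90	.	C	G	.	PASS	DP=120;AF=0.5	GT:AD	0/1:60,60
contig_3	5	.	G	A	.	PASS	DP=130;AF=0.35	GT:AD	0/1:85,45
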