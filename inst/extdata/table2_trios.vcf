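##fileformat=VCFv4.2
##reference=GRCh37
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##INFO=<ID=HGVSP,Number=1,Type=String,Description="Protein-level HGVS">
##INFO=<ID=HGVSC,Number=1,Type=String,Description="cDNA-level HGVS">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	P1	F1_fa	F1_mo	P2	F2_fa	F2_mo	P3	F3_fa	F3_mo	P4	P5	F4_fa	F4_mo	P7	P8	F5_mo	P6	F6_fa	F6_mo
11	88911122	.	A	G	.	PASS	GENE=TYR;HGVSP=p.(Met1Val);HGVSC=c.1A>G	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/1
11	88911261	.	G	A	.	PASS	GENE=TYR;HGVSP=p.(Gly47Asp);HGVSC=c.140G>A	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/1	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0
11	88911351	.	G	A	.	PASS	GENE=TYR;HGVSP=p.(Arg77Gln);HGVSC=c.230G>A	GT	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
11	88911407	.	A	AA	.	PASS	GENE=TYR;HGVSP=p.(Met96Asnfs*73);HGVSC=c.286dupA	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
11	88911446	.	G	A	.	PASS	GENE=TYR;HGVSP=p.(Gly109Arg);HGVSC=c.325G>A	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
11	88911576	.	C	G	.	PASS	GENE=TYR;HGVSP=p.(Pro152Arg);HGVSC=c.455C>G	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/0	0/0
11	88911696	.	C	A	.	PASS	GENE=TYR;HGVSP=p.(Ser192Tyr);HGVSC=c.575C>A	GT	1/1	1/1	0/1	0/1	0/1	0/0	0/0	0/0	0/0	0/1	0/1	1/1	0/0	0/1	0/1	1/1	0/1	1/1	0/1
11	88924200	.	T	C	.	PASS	GENE=TYR;HGVSP=p.(Cys247Arg);HGVSC=c.739T>C	GT	0/0	0/0	0/0	0/1	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
11	89017961	.	G	A	.	PASS	GENE=TYR;HGVSP=p.(Arg402Gln);HGVSC=c.1205G>A	GT	0/1	0/0	1/1	1/1	1/1	0/1	0/0	0/0	0/0	0/1	0/1	0/1	0/1	1/1	1/1	0/1	1/1	0/1	0/1
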