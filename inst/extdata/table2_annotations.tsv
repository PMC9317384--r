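hgvs_p	gene	consequence	maf_1000g	maf_evs	maf_dbsnp	maf_inhouse	gnomad_hom_or_hemi	pred_sift	pred_polyphen2	pred_mutation_taster	pred_mutation_assessor	pred_fathmm	pred_fathmm_mkl	in_clinvar_or_hgmd	splice_predicted_damaging	acmg_class
p.(Ser192Tyr)	TYR	missense	0.254	0.248	0.254	0.251	15632	benign	benign	benign	benign	benign	benign	FALSE	FALSE	B
p.(Arg402Gln)	TYR	missense	0.176	0.181	0.176	0.172	8417	damaging	benign	benign	benign	benign	benign	FALSE	FALSE	B
p.(Arg77Gln)	TYR	missense	0.0001	0	0.0001	0	0	damaging	damaging	damaging	damaging	damaging	damaging	TRUE	FALSE	P
p.(Cys247Arg)	TYR	missense	0	0	0	0	0	damaging	damaging	damaging	benign	damaging	damaging	TRUE	FALSE	P
p.(Met96Asnfs*73)	TYR	frameshift	0	0	0	0	0	missing	missing	damaging	missing	missing	damaging	TRUE	FALSE	P
p.(Gly109Arg)	TYR	missense	0	0	0.00005	0	0	damaging	damaging	damaging	damaging	damaging	damaging	TRUE	FALSE	P
p.(Gly47Asp)	TYR	missense	0.0002	0	0.0001	0.0003	0	damaging	damaging	damaging	damaging	benign	damaging	TRUE	FALSE	P
p.(Met1Val)	TYR	start_loss	0	0	0	0	0	damaging	damaging	damaging	missing	damaging	damaging	TRUE	FALSE	P
p.(Pro152Arg)	TYR	missense	0	0	0	0	0	damaging	damaging	damaging	damaging	damaging	damaging	FALSE	FALSE	P
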