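assay	description	n_cell_types	mark_group	category
H3K4me1	Regulatory mark associated with enhancer regions	111	active	histone_broad
H3K4me3	Regulatory mark associated with promoter regions	111	active	histone_broad
H3K9me3	Repressive mark associated with constitutive heterochromatin	111	repressive	histone_broad
H3K27me3	Repressive mark associated with Polycomb activity	111	repressive	histone_broad
H3K36me3	Elongation mark over transcribed gene bodies	111	repressive	histone_broad
H3K9ac	Acetylation at active enhancer and promoter regions	44	active	histone_broad
H3K27ac	Acetylation at active enhancer and promoter regions	82	active	histone_broad
DNAm	CpG methylation; gene silencing and repeat stability	40	dnam	dnam_cpg
DNase	Accessible chromatin (DNase I hypersensitivity)	37	accessibility	accessibility_narrow
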