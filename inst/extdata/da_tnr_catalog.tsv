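disease	disease_id	gene	chrom	pos_1based	unit	unit_count	exon	intron	utr5	utr3
Spinobulbar muscular atrophy	SBMA	AR	X	66765160	CAG	34	1	0	0	1
Huntington's disease	HD	HTT	4	3076604	CAG	21	1	0	0	0
Dentatorubral-pallidoluysian atrophy	DRPLA	ATN1	12	7045880	CAG	20	1	0	0	0
Spinocerebellar ataxia type 1	SCA1	ATXN1	6	16327213	CAG	29	1	1	0	0
Spinocerebellar ataxia type 2	SCA2	ATXN2	12	112037083	CAG	23	1	1	1	0
Spinocerebellar ataxia type 3	SCA3	ATXN3	14	92537280	CAG	27	1	0	1	1
Spinocerebellar ataxia type 6	SCA6	CACNA1A	19	13318283	CAG	13	1	0	0	1
Spinocerebellar ataxia type 7	SCA7	ATXN7	3	63898362	CAG	10	1	0	0	1
Spinocerebellar ataxia type 17	SCA17	TBP	6	170870996	CAG	47	1	0	0	0
Potassium channel gene	KCNN3	KCNN3	1	154841700	CAG	17	1	0	0	0
Amplified in breast cancer 1	AIB1	NCOA3	20	46279816	CAG	29	1	0	0	0
Soluble programmed death-1	SPD1	HOXD13	2	176957782	GCG	15	1	0	0	0
Oculopharyngeal muscular dystrophy	OPMD	PABPN1	14	23790681	GCG	7	1	1	0	0
Cleidocranial dysplasia, reduced bone mineral density	CBFA1	RUNX2	6	45390487	GCG	15	1	0	0	0
Holoprosencephaly	ZIC2	ZIC2	13	100637703	GCG	18	1	0	0	0
Hand-foot-genital syndrome	HOXA13	HOXA13	7	27238886	GCG	14	1	0	0	0
Blepharophimosis syndrome (BPES)	FOXL2	FOXL2	3	138665094	GCG	14	1	0	0	0
Early infantile epileptic encephalopathy type 1	EIEE1	ARX	X	25031140	GCG	15	1	0	0	0
Pseudoachondroplasia & multiple epiphyseal dysplasia	COMP	COMP	19	18896872	GAC	7	1	0	0	0
Fuchs' endothelial corneal dystrophy (FECD)	CTG18.1	TCF4	18	53253401	CAG	24	0	1	0	0
Myotonic dystrophy type 1	DM1	DMPK	19	46273199	CAG	20	0	0	0	1
Friedreich ataxia	FRDA	FXN	9	71652203	GAA	6	0	1	0	0
Spinocerebellar ataxia type 8	SCA8	ATXN8OS	13	70681356	CAG	15	1	0	0	1
Spinocerebellar ataxia type 12	SCA12	PPP2R2B	5	146258400	CAG	11	0	1	1	0
Huntington's disease-like 2	HDL2	JPH3	16	87637894	CAG	14	0	1	0	0
No phenotypic abnormality currently associated	MAB21L1	MAB21L1	13	36050618	CAG	19	0	1	1	0
Candidate gene for autism spectrum disorders (ASDs)	RELN	RELN	7	103629939	GCG	8	0	0	1	0
Fragile X syndrome/Fragile X tremor ataxia syndrome	FRAXA/FXTAS	FMR1	X	146993569	GCG	20	1	0	1	1
Folate-sensitive fragile site FRA10A	FRA10A	FRA10AC1	10	95462158	GCG	8	0	1	1	0
Fragile X syndrome	FRAXE	FMR2	X	147582153	GCG	19	0	0	1	0
Fragile X syndrome	FRAXF	FAM11A	X	148713314	GCG	12	0	0	1	0
Folate-sensitive fragile site FRA11B	FRA11B	CBL2	11	119077000	GCG	11	0	0	1	0
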