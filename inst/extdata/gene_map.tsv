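# Model node -> HUGO gene symbol used when matching expression data.
# Phenotype read-outs map to biomarker genes (Apoptosis -> CASP9,
# Migration -> CDC42, Invasion -> MMP2); GF and ERK map to the closest
# measured species (EGFR, MAPK1). Inputs and the EMT/Metastasis/
# CellCycleArrest read-outs have no transcript and are absent.
AKT1	AKT1
AKT2	AKT2
CDH1	CDH1
CDH2	CDH2
CTNNB1	CTNNB1
DKK1	DKK1
ERK	MAPK1
GF	EGFR
miR200	MIR200C
miR203	MIR203A
miR34	MIR34A
NICD	NOTCH1
p21	CDKN1A
p53	TP53
p63	TP63
p73	TP73
SMAD	SMAD3
SNAI1	SNAI1
SNAI2	SNAI2
TGFbeta	TGFB1
TWIST1	TWIST1
VIM	VIM
ZEB1	ZEB1
ZEB2	ZEB2
Apoptosis	CASP9
Migration	CDC42
Invasion	MMP2
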