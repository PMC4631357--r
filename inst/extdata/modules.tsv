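# Pathway modules of the metastasis model: module name -> member nodes.
# Pathway-level GoF/LoF mutants clamp every member simultaneously.
TGFb_pthw	TGFbeta,SMAD
Notch_pthw	NICD
WNT_pthw	DKK1,CTNNB1
p53	p53
p63_73	p63,p73
miRNA	miR34,miR200,miR203
EMT_reg	TWIST1,ZEB1,ZEB2,SNAI1,SNAI2,CDH2,VIM
Ecadh	CDH1
GF	GF
ERK_pthw	ERK
AKT1	AKT1
AKT2	AKT2
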