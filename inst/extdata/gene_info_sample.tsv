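symbol	synonyms
BRCA1	BRACA1|BRCAI|BRCC1|BROVCA1|FANCS|IRIS|PNCA4|PPP1R53|PSCP|RNF53
TP53	BCC7|BMFS5|LFS1|P53|TRP53
KIT	C-Kit|CD117|MASTC|PBT|SCFR
ERBB2	CD340|HER-2|HER2|NEU|NGL|TKR1
PTEN	-
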