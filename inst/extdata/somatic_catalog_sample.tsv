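symbol	entrez_id
BRCA1	672
TP53	7157
KIT	3815
ERBB2	2064
PTEN	5728
NOMAP1	999001
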