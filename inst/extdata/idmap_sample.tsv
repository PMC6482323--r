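entrez_id	human_gene_id
672	ENSG00000012048
7157	ENSG00000141510
3815	ENSG00000157404
2064	ENSG00000141736
5728	ENSG00000171862
1956	ENSG00000146648
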