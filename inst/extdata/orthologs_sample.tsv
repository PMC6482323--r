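human_gene_id	dog_gene_id	similarity	description
ENSG00000012048	ENSCAFG00000014600	85.2	BRCA1 DNA repair associated
ENSG00000141510	ENSCAFG00000008917	89.4	tumor protein p53
ENSG00000157404	ENSCAFG00000002306	91.1	KIT proto-oncogene receptor tyrosine kinase
ENSG00000141736	ENSCAFG00000012345	75.0	erb-b2 receptor tyrosine kinase 2
ENSG00000171862	ENSCAFG00000017662	74.9	phosphatase and tensin homolog
ENSG00000146648	ENSCAFG00000019282	88.0	epidermal growth factor receptor
ENSG00000999999	ENSCAFG00000099999	99.0	hypothetical non-catalog gene
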