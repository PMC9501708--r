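gene_symbol	species	accession	isoform_label	cds_length	source
CD14	Homo sapiens	SYN-CD14-HS	X1	180	fixture
CD14	Oryctolagus cuniculus	SYN-CD14-OC	X1	180	fixture
CD14	Mus musculus	SYN-CD14-MM	X1	180	fixture
IL10	Homo sapiens	SYN-IL10-HS	X1	300	fixture
IL10	Oryctolagus cuniculus	SYN-IL10-OC	X1	297	fixture
IL10	Mus musculus	SYN-IL10-MM	X1	300	fixture
TLR5	Homo sapiens	SYN-TLR5-HS	X1	150	fixture
TLR5	Oryctolagus cuniculus	SYN-TLR5-OC	X1	150	fixture
TLR5	Mus musculus	SYN-TLR5-MM	X1	150	fixture
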