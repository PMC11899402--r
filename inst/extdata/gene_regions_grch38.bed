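chr15	44711477	44718877	B2M
chr17	7668402	7687550	TP53
chr19	1205778	1228431	STK11
chr10	87863113	87971930	PTEN
chr12	25205246	25250929	KRAS
chr12	68808172	68850686	MDM2
chr1	204516379	204527248	MDM4
chr7	55019017	55211628	EGFR
chr1	64833223	64967543	JAK1
chr9	4984390	5129948	JAK2
chr3	41199422	41240445	CTNNB1
chr7	140719327	140924929	BRAF
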