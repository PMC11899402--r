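sample_id	braf_v600e	tumor_purity	ns_tmb	indel_burden	fsindel_burden	inframe_burden	splice_burden	missense_burden	synonymous_burden	multi_aa_burden	frameshift_proportion	dnds_ratio	cnv_burden	deletion_burden	neoantigen_burden	max_neo_affinity	dai_mean	dai_median	dai_max	dai_upper_decile	max_recognition_potential	max_hex	max_dissimilarity	hed_mean	hla_b27	hla_b44	hla_b62	hom_hla_b	hom_hla_c	alt_b2m	alt_tp53	alt_stk11	alt_pten	alt_kras	alt_mdm2	alt_mdm4	alt_egfr	response_pathway
WE01	1	0.8	2.5	1	0.5	0.5	0	1.5	0.5	0	0.2	2	0.25	0.25	1	-3.912023005	1.151292546	1.151292546	2.302585093	2.072326584	1.5	8	0.4	17.26666667	1	1	0	0	1	1	0	0	0	0	0	0	0	1
WE02	0	0.6	0	0	0	0	0	0	0	0	0	1	0	0	0	NA	NA	NA	NA	NA	NA	NA	NA	0	0	0	0	1	1	0	0	0	0	0	0	0	0	0
WE03	0	0.5	1.5	0	0	0	0.5	0.5	0	0.5	0	3	0.5	0	0.5	-5.991464547	-0.6931471806	-0.6931471806	-0.6931471806	-0.6931471806	2	5	0.9	19.1	0	0	1	0	0	0	1	0	0	1	1	0	0	1
WE04	0	0.9	0.5	0	0	0	0	0.5	0	0	0	2	0	0	0	NA	NA	NA	NA	NA	NA	NA	NA	0	0	1	0	1	1	0	0	0	0	0	0	0	0	0
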