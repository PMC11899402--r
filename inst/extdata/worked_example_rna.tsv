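sample_id	lymphocyte_infiltration	tcr_alpha_entropy	tcr_beta_entropy	igh_entropy	ifng_ims_ratio	fusion_neoepitope_count	gep_hla_class1	gep_pdl1	gep_b2m
WE01	2	1.039720771	0.6931471806	0	3.999994	1	2.333333333	1	4
WE02	0	0	0	0	6.666662222e-07	0	1	0	2
WE03	2	1.386294361	0.5623351446	0.6931471806	1.999999	0	1.333333333	3	3
WE04	1	0	0	0.9502705392	1	2	0	2	1
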