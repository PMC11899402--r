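# Hand-derived expected biomarker values for the worked-example cohort.
# Every value below is written as the explicit arithmetic a reviewer would
# do on paper; only the shipped Grantham table is looked up.
library(iciomics)
gm <- grantham_matrix()
dSR <- gm["S","R"]; dCW <- gm["C","W"]; dAC <- gm["A","C"]
dED <- gm["E","D"]; dLM <- gm["L","M"]
cat("Grantham lookups: S-R", dSR, "C-W", dCW, "A-C", dAC, "E-D", dED, "L-M", dLM, "\n")

dna <- rbind(
  WE01 = c(braf_v600e = 1, tumor_purity = 0.8,
           ns_tmb = 5/2, indel_burden = 2/2, fsindel_burden = 1/2,
           inframe_burden = 1/2, splice_burden = 0, missense_burden = 3/2,
           synonymous_burden = 1/2, multi_aa_burden = 0,
           frameshift_proportion = 1/5, dnds_ratio = (3+1)/(1+1),
           cnv_burden = 0.5e6/2e6, deletion_burden = 0.5e6/2e6,
           neoantigen_burden = 2/2, max_neo_affinity = -log(50),
           dai_mean = (log(500/50) + log(100/100))/2,
           dai_median = (log(10) + 0)/2, dai_max = log(10),
           dai_upper_decile = 0 + 0.9*(log(10) - 0),
           max_recognition_potential = 1.5, max_hex = 8,
           max_dissimilarity = 0.4,
           hed_mean = (dSR/10 + (dCW + dAC)/10 + 0)/3,
           hla_b27 = 1, hla_b44 = 1, hla_b62 = 0, hom_hla_b = 0,
           hom_hla_c = 1, alt_b2m = 1, alt_tp53 = 0, alt_stk11 = 0,
           alt_pten = 0, alt_kras = 0, alt_mdm2 = 0, alt_mdm4 = 0,
           alt_egfr = 0, response_pathway = 1),
  WE02 = c(0, 0.6, 0,0,0,0,0,0,0,0, 0, (0+1)/(0+1), 0, 0,
           0, NA, NA, NA, NA, NA, NA, NA, NA,
           0, 0,0,0,1,1, 0,0,0,0,0,0,0,0, 0),
  WE03 = c(0, 0.5, 3/2, 0, 0, 0, 1/2, 1/2, 0, 1/2,
           0/3, (2+1)/(0+1), 1e6/2e6, 0,
           1/2, -log(400), log(200/400), log(0.5), log(0.5), log(0.5),
           2, 5, 0.9,
           (dSR/10 + 10*dED/10 + dLM/10)/3,
           0, 0, 1, 0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1),
  WE04 = c(0, 0.9, 1/2, 0, 0, 0, 0, 1/2, 0, 0,
           0, (1+1)/(0+1), 0, 0,
           0, NA, NA, NA, NA, NA, NA, NA, NA,
           0, 0, 1, 0, 1, 1, 0,0,0,0,0,0,0,0, 0))
colnames(dna) <- dna_feature_names()

eps <- 1e-6
H <- function(p) -sum(p*log(p))
rna <- rbind(
  WE01 = c(lymphocyte_infiltration = (log2(3+1)+log2(3+1))/2,
           tcr_alpha_entropy = H(c(2,1,1)/4),
           tcr_beta_entropy = H(c(1,1)/2),
           igh_entropy = 0,
           ifng_ims_ratio = ((log2(7+1)+log2(1+1))/2 + eps) /
                            ((log2(0+1)+log2(1+1))/2 + eps),
           fusion_neoepitope_count = 1,
           gep_hla_class1 = (log2(8)+log2(8)+log2(2))/3,
           gep_pdl1 = log2(1+1), gep_b2m = log2(15+1)),
  WE02 = c(0, 0, 0, 0,
           (0 + eps)/((log2(3+1)+log2(1+1))/2 + eps),
           0, (log2(2)+log2(2)+log2(2))/3, 0, log2(3+1)),
  WE03 = c((log2(7+1)+log2(1+1))/2,
           H(rep(1/4,4)), H(c(3,1)/4), H(c(2,2)/4),
           ((log2(3+1)+log2(3+1))/2 + eps)/((log2(1+1)+log2(1+1))/2 + eps),
           0, (log2(4)+log2(2)+log2(2))/3, log2(7+1), log2(7+1)),
  WE04 = c((log2(1+1)+log2(1+1))/2, 0, 0, H(c(1,1,3)/5),
           ((log2(1+1)+log2(0+1))/2 + eps)/((log2(1+1)+log2(0+1))/2 + eps),
           2, 0, log2(3+1), log2(1+1)))
colnames(rna) <- rna_feature_names()

write_feature_matrix(dna, "inst/extdata/worked_example_dna.tsv")
write_feature_matrix(rna, "inst/extdata/worked_example_rna.tsv")
cat("written\n")
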