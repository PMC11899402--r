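#!/usr/bin/env Rscript
# QC the simulated cohort (sample, variant and CNV filters), build the
# meta-cohort target region, batch-correct expression, and derive the 38
# genomic + 9 transcriptomic biomarkers. Writes results/dna_features.tsv
# and results/rna_features.tsv.
suppressMessages(library(iciomics))

cohort <- read_cohort("results/cohort")
feats <- prepare_cohort_features(cohort)
message(sprintf("target region after sub-cohort intersection: %.2f Mb",
                feats$target_mb))
message(sprintf("samples excluded by QC: %d | variants removed: %d",
                nrow(feats$excluded), nrow(feats$removed_variants)))
message(sprintf("feature matrices: DNA %d x %d, RNA %d x %d",
                nrow(feats$dna), ncol(feats$dna),
                nrow(feats$rna), ncol(feats$rna)))
write_feature_matrix(feats$dna, "results/dna_features.tsv")
write_feature_matrix(feats$rna, "results/rna_features.tsv")
saveRDS(feats, "results/features.rds")  # scratch hand-off to later steps
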