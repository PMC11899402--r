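#!/usr/bin/env Rscript
# Per-sample SHAP explanations of the multi-omics model over the complete
# paired cohort, the TP/TN group-difference table (Mann-Whitney +
# Bonferroni), and a force decomposition of one representative true
# positive and true negative. Writes results/shap_*.tsv.
suppressMessages(library(iciomics))

feats <- readRDS("results/features.rds")
st <- readRDS("results/models.rds")
casc <- st$cascade; labels <- st$labels; samples <- st$samples
tr <- samples$sample_id[samples$split == "train"]
paired_all <- intersect(rownames(feats$dna), rownames(feats$rna))
paired_tr <- intersect(tr, paired_all)

shap <- linear_shap(casc$multi,
                    multiomics_matrix(casc, feats$dna, feats$rna, paired_all),
                    background = multiomics_matrix(casc, feats$dna, feats$rna,
                                                   paired_tr),
                    y = labels[paired_all])
write.table(data.frame(sample_id = rownames(shap$shap), group = shap$groups,
                       prediction = shap$predictions, shap$shap,
                       check.names = FALSE),
            "results/shap_values.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
gd <- group_difference(shap)
gd[, sapply(gd, is.numeric)] <- signif(gd[, sapply(gd, is.numeric)], 4)
print(gd[order(gd$p_adjusted), ], row.names = FALSE)
write.table(gd, "results/shap_group_difference.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sum(gd$significant),
        " biomarkers discriminate TP from TN after Bonferroni correction")

tp <- names(shap$groups)[shap$groups == "TP"][1]
tn <- names(shap$groups)[shap$groups == "TN"][1]
for (s in c(tp, tn)) {
  fd <- force_decomposition(shap, s)
  message("force decomposition for ", s, " (", shap$groups[[s]], "): ",
          paste(sprintf("%s %+0.3f", fd$feature, fd$shap), collapse = ", "))
}
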