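#!/usr/bin/env Rscript
# Split the cohort (stratified by response and the 10 mut/Mb nsTMB bin,
# test set drawn from paired samples only), train the DNA and RNA LASSO
# models, gate their features by permutation importance > 0.0055, and
# train the multi-omics model on the gated union. Writes the three model
# bundles and importance tables under results/.
suppressMessages(library(iciomics))

seed <- 20240901
feats <- readRDS("results/features.rds")
samples <- split_cohort(feats$samples, feats$nstmb, seed = seed + 101)
write_sample_sheet(samples, "results/split.tsv")
labels <- setNames(as.numeric(samples$response == "responder"),
                   samples$sample_id)
tr <- samples$sample_id[samples$split == "train"]
dna_tr <- feats$dna[intersect(tr, rownames(feats$dna)), ]
rna_tr <- feats$rna[intersect(tr, rownames(feats$rna)), ]
casc <- train_cascade(dna_tr, rna_tr, labels,
                      intersect(rownames(dna_tr), rownames(rna_tr)),
                      cascade_config(seed = seed + 202))
message("DNA model: alpha ", signif(casc$dna$alpha, 3), ", ",
        sum(casc$dna$coefficients != 0), " non-zero coefficients; gated: ",
        paste(casc$selected_dna, collapse = ", "))
message("RNA model: alpha ", signif(casc$rna$alpha, 3), "; gated: ",
        paste(casc$selected_rna, collapse = ", "))
message("multi-omics model on ", length(casc$multi$feature_names),
        " features, threshold ", signif(casc$multi$prob_threshold, 3))
for (m in c("dna", "rna", "multi")) {
  write_model(casc[[m]], file.path("results", paste0(m, "_model.json")))
}
write.table(casc$importance_dna, "results/importance_dna.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(casc$importance_rna, "results/importance_rna.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(list(cascade = casc, samples = samples, labels = labels),
        "results/models.rds")
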