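#!/usr/bin/env Rscript
# Stage 3: pruned-set genotype PCA, PC retention and subpopulation
# clustering. Writes eigenvalues, PC coordinates and cluster labels.

library(varbatch)

ds <- read_dataset("results/simdata")
sqc <- read.table("results/qc/sample_qc.tsv", header = TRUE, sep = "\t")
retained <- as.integer(readLines("results/qc/retained_variants.txt"))
dir.create("results/structure", recursive = TRUE, showWarnings = FALSE)

calls <- subset_call_set(ds$calls, samples = which(sqc$pass))
samples <- ds$samples[sqc$pass, ]

pruned <- build_pruned_set(calls, qc_thresholds(), retained)
cat(length(pruned), "variants in the pruned PCA set\n")

pca <- genotype_pca(calls, variants = pruned)
n_pcs <- retain_pcs(pca)
cat("leading eigenvalues:", paste(sprintf("%.2f", head(pca$values, 6)),
                                  collapse = ", "), "\n")
cat("retained PCs (eigenvalue > 1, capped):", n_pcs, "\n")

cl <- cluster_subpops(pca, k_range = 1:6, seed = 1L)
cat("silhouette-chosen subpopulation count:", cl$k, "\n")
if (!is.null(ds$truth)) {
  cat("cross-tabulation against truth subpopulations:\n")
  print(table(cluster = cl$labels, truth = ds$truth$subpop[sqc$pass]))
}

write.table(
  data.frame(sample_id = samples$sample_id,
             pca$vectors[, 1:min(6, ncol(pca$vectors))],
             cluster = cl$labels),
  "results/structure/pcs.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(as.character(pruned), "results/structure/pruned_variants.txt")
writeLines(format(pca$values, digits = 8), "results/structure/eigenvalues.txt")
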