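#!/usr/bin/env Rscript
# Stage 2: sample-level QC and variant-level filters for association.
# Reads the Stage-1 dataset, writes pass/fail tables and filter counts.

library(varbatch)

ds <- read_dataset("results/simdata")
dir.create("results/qc", recursive = TRUE, showWarnings = FALSE)

thr <- qc_thresholds()
sqc <- sample_qc(ds$calls, thr)
write.table(sqc, "results/qc/sample_qc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sum(sqc$pass), "of", nrow(sqc), "samples pass sample-level QC\n")
if (any(!sqc$pass)) print(table(sqc$reasons[!sqc$pass]))

calls <- subset_call_set(ds$calls, samples = which(sqc$pass))
samples <- ds$samples[sqc$pass, ]
vf <- variant_filters(calls, samples$phenotype == "control", thr)
cat(length(vf$retained), "of", n_variants(calls),
    "variants retained for association\n")
cat("exclusion counts:", paste(names(vf$counts), vf$counts, sep = "=",
                               collapse = ", "), "\n")
jsonlite::write_json(
  list(retained = length(vf$retained), counts = as.list(vf$counts)),
  "results/qc/variant_filters.json", auto_unbox = TRUE, pretty = TRUE)
writeLines(as.character(vf$retained), "results/qc/retained_variants.txt")
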