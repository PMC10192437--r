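#!/usr/bin/env Rscript
# Depletion analysis of the simulated screen from 01_simulate_screen.R:
# TPM normalization, selected/input fold changes, empirical-null p-values
# against the non-targeting controls, depletion calls at the stringent
# thresholds (fold change < 0.5 and p < 0.005), gene aggregation with the
# gene-level KS test, and library-diversity summaries.

library(invascreen)

if (!file.exists("results/screen_counts.tsv")) {
  stop("run analysis/01_simulate_screen.R first")
}
counts <- read_counts("results/screen_counts.tsv")
truth <- read.table("results/screen_truth.tsv", header = TRUE, sep = "\t")

tpm <- tpm_normalize(counts)
rec <- sgrna_fold_changes(tpm, "Input", "Selected", counts)
rec <- sgrna_depletion_pvalues(rec, null_source = "ntc")
rec <- call_depleted(rec, depletion_thresholds(fc_thresh = 0.5,
                                               p_thresh = 0.005))
genes <- aggregate_genes(rec, min_depleted = 1)

write.table(rec, "results/guide_depletion.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(genes, "results/gene_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cf_in <- cumulative_frequency(counts, "Input")
cf_sel <- cumulative_frequency(counts, "Selected")
write.table(cbind(sample = "Input", cf_in$curve),
            "results/lorenz_input.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cbind(sample = "Selected", cf_sel$curve),
            "results/lorenz_selected.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

drivers <- truth$gene[truth$driver]
called <- genes$gene
cat(sprintf("significantly depleted sgRNAs: %d of %d\n",
            sum(rec$depleted), nrow(rec)))
cat(sprintf("genes with >=1 depleted guide: %d (%.1f guides/gene)\n",
            nrow(genes), sum(rec$depleted) / max(1, nrow(genes))))
cat(sprintf("driver recall: %.1f%%; false gene calls: %.1f%%\n",
            100 * mean(drivers %in% called),
            if (length(called)) 100 * mean(!(called %in% drivers)) else 0))
cat(sprintf("library Gini: input %.3f -> selected %.3f; zero-count guides:",
            cf_in$gini, cf_sel$gini),
    sprintf("%.2f%% -> %.2f%%\n", 100 * cf_in$zero_fraction,
            100 * cf_sel$zero_fraction))
cat("wrote results/guide_depletion.tsv, results/gene_summary.tsv,",
    "results/lorenz_*.tsv\n")
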