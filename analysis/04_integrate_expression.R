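#!/usr/bin/env Rscript
# Integration screens: (1) intersect the depleted-gene list from the CRISPR
# screen with the up-regulated genes of an invasive-subline expression
# profile (fold change > 2, FDR < 0.001); (2) scan a 3'UTR for miRNA seed
# sites and intersect with down-regulated miRNAs.

library(invascreen)

if (!file.exists("results/gene_summary.tsv")) {
  stop("run analysis/03_call_depletion.R first")
}
genes_tab <- read.table("results/gene_summary.tsv", header = TRUE, sep = "\t")
truth <- read.table("results/screen_truth.tsv", header = TRUE, sep = "\t")
seed <- 1L

## screen x expression overlap: 17 drivers planted as up-regulated
all_genes <- truth$gene[truth$gene != "NTC"]
drivers <- truth$gene[truth$driver]
up_set <- c(drivers[1:17], setdiff(all_genes, drivers)[1:100])
de <- simulate_expression(all_genes, up_set, true_fc = 4, seed = seed + 100)
up_called <- de_upregulated(de, fc_min = 2.0, q_max = 0.001)
cand <- overlap_candidates(genes_tab, de[de$gene %in% up_called, ])
write.table(cand, "results/overlap_candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("up-regulated genes (FC>2, q<0.001): %d of %d\n",
            length(up_called), length(all_genes)))
cat(sprintf("overlap of screen hits x up-regulated: %d genes\n", nrow(cand)))
cat("top candidates:\n")
print(head(cand[, c("gene", "rank", "n_depleted", "ks_p", "fold_change")]),
      row.names = FALSE)

## miRNA candidate screen on a UTR with two planted 8mer sites
mir449a <- "UGGCAGUGUCUUAGCUGGUUGU"
decoys <- c("miR-100" = "AACCCGUAGAUCCGAACUUGUG",
            "miR-200" = "UAACACUGUCUGGUAACGAUGU")
pl <- make_planted_utr(mir449a, "8mer", utr_len = 1500, n_sites = 2,
                       seed = seed + 200)
sites <- seed_scan(pl$utr_seq, c(c("miR-449a" = mir449a), decoys))
cands <- mirna_candidates(sites, down_mirnas = c("miR-449a", "miR-100"))
write.table(sites, "results/utr_seed_sites.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cands, "results/mirna_candidates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("\nseed sites found in the %d-nt UTR: %d (planted 8mers: %d)\n",
            nchar(pl$utr_seq), nrow(sites),
            sum(sites$site_type == "8mer")))
cat(sprintf("candidate miRNAs (sites + down-regulated): %s\n",
            paste(cands$mirna_id, collapse = ", ")))
cat("wrote results/overlap_candidates.tsv, results/utr_seed_sites.tsv,",
    "results/mirna_candidates.tsv\n")
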