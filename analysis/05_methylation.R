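#!/usr/bin/env Rscript
# Promoter methylation analysis: predict CpG islands in a synthetic promoter
# (a CpG-dense core inside AT-rich flanks), simulate bisulfite pileups for a
# tumor-like (heavily methylated) and normal-like (lightly methylated)
# profile, summarize per-site fractions under the depth >= 4 rule, and
# classify the region difference.

library(invascreen)

dir.create("results", showWarnings = FALSE)
seed <- 1L

set.seed(seed + 300)
flank <- function(n) paste0(sample(c("A", "C", "G", "T"), n, TRUE,
                                   c(.35, .15, .15, .35)), collapse = "")
promoter <- paste0(flank(600), strrep("CG", 150), flank(600))

islands <- find_cpg_islands(promoter, window = 200, min_len = 200,
                            min_gc = 0.5, min_oe = 0.6)
write.table(cbind(chrom = "promoter", islands), "results/cpg_islands.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("CpG islands predicted in the %d-bp promoter: %d\n",
            nchar(promoter), nrow(islands)))
print(islands, row.names = FALSE)

isl <- islands[1, ]
cpg_pos <- isl$start + 2 * (seq_len(50) - 1)
tumor <- site_methylation(simulate_bisulfite(
  "promoter", cpg_pos, 0.85, mean_depth = 30, seed = seed + 301))
normal <- site_methylation(simulate_bisulfite(
  "promoter", cpg_pos, 0.10, mean_depth = 30, seed = seed + 302))
write.table(tumor, "results/pileup_tumor.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(normal, "results/pileup_normal.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

region <- list(chrom = "promoter", start = isl$start, end = isl$end)
seq_isl <- substr(promoter, isl$start + 1, isl$end)
st_t <- region_meth_stats(region, seq_isl, tumor)
st_n <- region_meth_stats(region, seq_isl, normal)
stats <- rbind(cbind(profile = "tumor", st_t),
               cbind(profile = "normal", st_n))
write.table(stats, "results/region_meth_stats.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("island [%d, %d): CpG density %.3f, GC %.3f\n",
            isl$start, isl$end, st_t$cpg_density, st_t$gc_content))
cat(sprintf("mean methylation (depth>=4 sites): tumor %.3f vs normal %.3f\n",
            st_t$mean_meth_fraction, st_n$mean_meth_fraction))
cat(sprintf("classification (delta = 0.25): %s\n",
            compare_methylation(st_t, st_n)))
cat("wrote results/cpg_islands.tsv, results/pileup_*.tsv,",
    "results/region_meth_stats.tsv\n")
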