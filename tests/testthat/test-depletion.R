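rec_df <- function(gene, log2fc, fc = 2^log2fc, p = NA_real_) {
  data.frame(sgrna_id = sprintf("sg_%03d", seq_along(gene)), gene = gene,
             tpm_input = 100, tpm_selected = 100 * fc, fc = fc,
             log2fc = log2fc, p = p, depleted = NA,
             stringsAsFactors = FALSE)
}

test_that("TPM normalization applies the printed formula and sums to 1e6", {
  m <- matrix(c(5L, 15L, 80L), ncol = 1,
              dimnames = list(paste0("sg", 1:3), "S"))
  expect_equal(unname(tpm_normalize(m)[, 1]), c(50000, 150000, 800000))

  one <- matrix(7L, dimnames = list("sg1", "S"))
  expect_equal(unname(tpm_normalize(one)[1, 1]), 1e6)

  set.seed(3)
  big <- matrix(rpois(600, 40), ncol = 3,
                dimnames = list(sprintf("sg%03d", 1:200), c("A", "B", "C")))
  expect_equal(unname(colSums(tpm_normalize(big))), rep(1e6, 3),
               tolerance = 1e-6)
  # scale invariance per sample
  big2 <- big
  big2[, 2] <- big2[, 2] * 17L
  expect_equal(tpm_normalize(big2)[, 2], tpm_normalize(big)[, 2])

  zero <- big; zero[, 2] <- 0L
  expect_error(tpm_normalize(zero), "B")
})

test_that("fold changes use the pseudocount on both sides", {
  tpm <- matrix(c(100, 99, 50, 100, 0, 0), ncol = 2,
                dimnames = list(c("sg1", "sg2", "sg3"),
                                c("Input", "Selected")))
  gene <- c(sg1 = "A", sg2 = "A", sg3 = "B")
  rec <- sgrna_fold_changes(tpm, "Input", "Selected", gene)
  expect_equal(rec$fc[1], 1)        # equal TPM -> fc 1, log2fc 0
  expect_equal(rec$log2fc[1], 0)
  expect_equal(rec$fc[2], (0 + 1) / (99 + 1))   # 0.01
  expect_lt(rec$fc[3], 1)           # present in input, absent in selected
  expect_error(sgrna_fold_changes(tpm, "Input", "Nope", gene), "unknown")
})

test_that("empirical-null p-values follow the add-one tail formula", {
  ntc_vals <- seq(-0.5, 0.5, length.out = 999)
  rec <- rec_df(c(rep("NTC", 999), "G1"), c(ntc_vals, -5))
  rec <- sgrna_depletion_pvalues(rec, "ntc")
  expect_equal(rec$p[1000], 1 / 1000)     # below all 999 NTC values
  expect_true(all(rec$p > 0 & rec$p <= 1))

  rec2 <- rec_df(c(rep("NTC", 999), "G1"), c(ntc_vals, median(ntc_vals)))
  rec2 <- sgrna_depletion_pvalues(rec2, "ntc")
  expect_equal(rec2$p[1000], 0.501, tolerance = 0.01)

  rec3 <- rec_df(rep("G1", 60), rep(0.2, 60))
  rec3 <- sgrna_depletion_pvalues(rec3, "all")
  expect_true(all(rec3$p == 1))           # degenerate: all identical

  expect_error(sgrna_depletion_pvalues(rec_df("G1", 0), "ntc"), "empty")
})

test_that("NTC p-values are super-uniform under the neutral screen", {
  pvals <- unlist(lapply(1:5, function(seed) {
    s <- small_screen(n_genes = 20, n_ntc = 500, n_drivers = 0,
                      reads = 3e5, seed = seed)
    tpm <- tpm_normalize(s$sim$counts)
    rec <- sgrna_fold_changes(tpm, "Input", "Selected", s$sim$counts)
    rec <- sgrna_depletion_pvalues(rec, "ntc")
    rec$p[rec$gene == "NTC"]
  }))
  n_null <- 500
  for (alpha in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    slack <- 1 / (n_null + 1) + 3 * sqrt(alpha * (1 - alpha) / length(pvals))
    expect_lte(mean(pvals <= alpha), alpha + slack)
  }
})

test_that("depletion calls use strict thresholds on both axes", {
  rec <- rec_df(rep("G", 4), log2(c(0.4, 0.5, 0.4, 0.49)),
                p = c(0.001, 0.0001, 0.005, 0.0049))
  rec <- call_depleted(rec)
  expect_equal(rec$depleted, c(TRUE, FALSE, FALSE, TRUE))
  expect_error(call_depleted(rec_df("G", 0)), "populated")
})

test_that("gene-level KS agrees with exhaustive enumeration for n <= 10", {
  rec <- rec_df(c(rep("G", 3), rep("B", 5)),
                c(-2, -1.5, -1, 0, 0.1, -0.1, 0.2, -0.2))
  ks <- gene_ks_test(rec, "G")
  expect_equal(ks$ks_D, 1)
  oracle <- ks_oracle(c(-2, -1.5, -1), c(0, 0.1, -0.1, 0.2, -0.2))
  expect_equal(ks$ks_p, oracle$p)          # 2 / choose(8, 3)

  set.seed(11)
  for (i in 1:15) {
    m <- sample(2:5, 1)
    n <- sample(2:(10 - m), 1)
    vals <- round(stats::rnorm(m + n), 4)
    while (anyDuplicated(vals)) vals <- round(stats::rnorm(m + n), 4)
    rec <- rec_df(c(rep("G", m), rep("B", n)), vals)
    ks <- gene_ks_test(rec, "G")
    oracle <- ks_oracle(vals[1:m], vals[-(1:m)])
    expect_equal(ks$ks_D, oracle$D, tolerance = 1e-12)
    expect_equal(ks$ks_p, oracle$p, tolerance = 1e-9)
  }
  expect_error(gene_ks_test(rec_df(c("G", "B", "B"), c(0, 1, 2)), "G"),
               ">= 2 guides")
})

test_that("null gene KS is unremarkable and separated genes give D = 1", {
  set.seed(5)
  rec <- rec_df(c(rep("G", 6), rep("B", 200)), stats::rnorm(206))
  ks <- gene_ks_test(rec, "G")
  expect_lt(ks$ks_D, 0.6)
  expect_gt(ks$ks_p, 0.05)
  rec2 <- rec_df(c(rep("G", 4), rep("B", 50)),
                 c(-9, -8, -7, -6, stats::rnorm(50)))
  expect_equal(gene_ks_test(rec2, "G")$ks_D, 1)
})

test_that("gene aggregation tallies, filters and sorts", {
  rec <- rec_df(c(rep("G1", 6), rep("G2", 6), rep("B", 60)),
                c(rep(-3, 3), rep(0, 3), rep(-3, 5), rep(0, 1),
                  rep(0, 60)))
  rec$p <- ifelse(rec$log2fc < -1, 0.001, 0.9)
  rec <- call_depleted(rec)
  gs <- aggregate_genes(rec, min_depleted = 1)
  expect_equal(gs$gene, c("G2", "G1"))     # more depleted guides first
  expect_equal(gs$n_depleted, c(5L, 3L))
  expect_equal(gs$n_sgrnas, c(6L, 6L))
  gs4 <- aggregate_genes(rec, min_depleted = 4)
  expect_equal(gs4$gene, "G2")
  expect_equal(nrow(aggregate_genes(rec, min_depleted = 6)), 0)
})

test_that("Lorenz curve, Gini and dropout fraction behave as closed forms", {
  n <- 10
  uni <- matrix(rep(100L, n), ncol = 1,
                dimnames = list(paste0("sg", 1:n), "S"))
  cf <- cumulative_frequency(uni, "S")
  expect_equal(cf$gini, 0, tolerance = 1e-12)
  expect_equal(cf$zero_fraction, 0)

  onept <- matrix(c(rep(0L, n - 1), 500L), ncol = 1,
                  dimnames = list(paste0("sg", 1:n), "S"))
  cf <- cumulative_frequency(onept, "S")
  expect_equal(cf$gini, 1 - 1 / n)
  expect_equal(cf$zero_fraction, (n - 1) / n)

  s <- small_screen(n_genes = 50, n_ntc = 0, n_drivers = 25, fitness = 0.1,
                    reads = 3e5, seed = 2)
  g_in <- cumulative_frequency(s$sim$counts, "Input")$gini
  g_sel <- cumulative_frequency(s$sim$counts, "Selected")$gini
  expect_gt(g_sel, g_in)                  # selection reduces diversity

  zero <- matrix(0L, 2, 1, dimnames = list(c("a", "b"), "S"))
  expect_error(cumulative_frequency(zero, "S"), "zero total")
})
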