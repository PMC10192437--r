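test_that("up-regulation thresholds are strict and BH matches the formula", {
  de <- data.frame(gene = c("A", "B", "C"),
                   fold_change = c(2.5, 2.0, 3.0),
                   q = c(5e-4, 1e-5, 1e-3))
  expect_equal(de_upregulated(de), "A")  # B: fc == 2 excluded; C: q == 1e-3

  de2 <- data.frame(gene = paste0("g", 1:4), fold_change = 10,
                    p = c(0.001, 0.01, 0.02, 0.04))
  # hand BH: q_i = min_{j >= i} p_j * n / j
  expect_equal(stats::p.adjust(de2$p, "BH"), c(0.004, 0.02, 0.8 / 30, 0.04))
  up <- de_upregulated(de2, q_max = 0.021)
  expect_equal(up, c("g1", "g2"))
  expect_error(de_upregulated(de2[0, ]), "empty")
})

test_that("BH q-values are monotone in p-rank and never below p", {
  set.seed(8)
  p <- runif(200)^2
  q <- stats::p.adjust(p, "BH")
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
  expect_true(all(q >= p - 1e-12))
})

test_that("candidate overlap is the ranked intersection", {
  gs <- data.frame(gene = c("A", "B", "C"),
                   n_sgrnas = 6, n_depleted = c(4L, 6L, 2L),
                   mean_log2fc = -2, ks_D = 0.9,
                   ks_p = c(0.01, 0.001, 0.04))
  de <- data.frame(gene = c("B", "C", "D"), fold_change = c(3, 8, 2),
                   q = 1e-4)
  out <- overlap_candidates(gs, de)
  expect_equal(out$gene, c("B", "C"))     # intersection, n_depleted desc
  expect_equal(out$rank, 1:2)
  expect_true(all(out$gene %in% gs$gene) && all(out$gene %in% de$gene))

  none <- overlap_candidates(gs, data.frame(gene = "Z", fold_change = 2))
  expect_equal(nrow(none), 0)

  # ties on screen fields break by DE fold change, then gene name
  gs2 <- data.frame(gene = c("A", "B"), n_sgrnas = 6, n_depleted = 3L,
                    mean_log2fc = -1, ks_D = 0.5, ks_p = 0.01)
  de2 <- data.frame(gene = c("A", "B"), fold_change = c(2.5, 9), q = 1e-4)
  expect_equal(overlap_candidates(gs2, de2)$gene, c("B", "A"))
})

test_that("seed sites are classified by register with correct coordinates", {
  mir <- "UAAGGCACGC"                     # seed(2-8) match in UTR: GUGCCUU
  utr <- paste0("CCCCC", "GTGCCTTA", "CCCCC")  # one 8mer at 0-based 5
  hits <- seed_scan(utr, c(m1 = mir))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$site_type, "8mer")
  expect_equal(c(hits$start, hits$end), c(5L, 13L))

  # same site without the A -> 7mer-m8 (7 nt); without m8 base -> 7mer-A1
  h2 <- seed_scan(paste0("CCCCC", "GTGCCTTC", "CCCCC"), c(m1 = mir))
  expect_equal(h2$site_type, "7mer-m8")
  expect_equal(h2$end - h2$start, 7L)
  h3 <- seed_scan(paste0("CCCCC", "TTGCCTTA", "CCCCC"), c(m1 = mir))
  expect_equal(h3$site_type, "7mer-A1")
  expect_equal(h3$end - h3$start, 7L)

  expect_equal(nrow(seed_scan(strrep("A", 50), c(m1 = mir))), 0)
  expect_error(seed_scan(utr, c(m1 = "ACGU")), "shorter")
})

test_that("seed_scan equals the naive substring oracle on random UTRs", {
  set.seed(21)
  mirs <- c(m1 = "UAAGGCACGC", m2 = "UGGCAGUGUCUUAGCUGGUUGU",
            m3 = "ACGUACGUACGU")
  for (i in 1:4) {
    utr <- random_seq(5000)
    got <- seed_scan(utr, mirs)
    for (id in names(mirs)) {
      want <- naive_seed_scan(utr, id, mirs[[id]])
      sub <- got[got$mirna_id == id, c("start", "end", "site_type")]
      rownames(sub) <- NULL; rownames(want) <- NULL
      expect_equal(sub, want[, c("start", "end", "site_type")])
    }
  }
})

test_that("planted UTRs contain exactly the planted sites", {
  mir <- "UGGCAGUGUCUUAGCUGGUUGU"         # miR-449a-like
  pl <- make_planted_utr(mir, "8mer", utr_len = 800, n_sites = 2, seed = 3)
  hits <- seed_scan(pl$utr_seq, c(m = mir))
  expect_equal(nrow(hits), 2)
  expect_equal(sort(hits$start), sort(pl$sites$start))
  expect_true(all(hits$site_type == "8mer"))

  pl7 <- make_planted_utr(mir, "7mer-m8", utr_len = 600, n_sites = 1, seed = 5)
  h7 <- seed_scan(pl7$utr_seq, c(m = mir))
  expect_equal(h7$site_type, "7mer-m8")   # planted 7mer-m8 is not an 8mer

  pl0 <- make_planted_utr(mir, "8mer", utr_len = 400, n_sites = 0, seed = 1)
  expect_equal(nrow(seed_scan(pl0$utr_seq, c(m = mir))), 0)

  expect_error(make_planted_utr(mir, "8mer", utr_len = 10, n_sites = 2),
               "too small")
})

test_that("miRNA candidates are filtered by down-regulation and ranked", {
  sites <- data.frame(
    mirna_id = c("m1", "m2", "m2", "m2", "m3"),
    start = 1:5, end = 9:13,
    site_type = c("8mer", "7mer-A1", "7mer-A1", "7mer-A1", "8mer"))
  out <- mirna_candidates(sites, c("m1", "m2"))
  expect_equal(out$mirna_id, c("m1", "m2"))  # one 8mer beats three 7mer-A1
  expect_equal(out$best_class, c("8mer", "7mer-A1"))
  expect_equal(out$n_sites, c(1L, 3L))
  expect_equal(nrow(mirna_candidates(sites, character(0))), 0)
  expect_equal(mirna_candidates(sites, c("m2", "m9"))$mirna_id, "m2")
})
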