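test_that("staining scores dichotomize 0/1 low vs 2/3 high", {
  expect_equal(dichotomize(c(0, 1, 2, 3)), c("low", "low", "high", "high"))
  expect_error(dichotomize(4), "0..3")
})

test_that("paired up-regulation fraction counts strict ratios", {
  set.seed(2)
  normal <- runif(40, 1, 2)
  tumor <- normal
  tumor[1:31] <- tumor[1:31] * 1.5
  out <- paired_upregulation_fraction(tumor, normal)
  expect_equal(out$n_up, 31)
  expect_equal(out$percent, 77.5)
  eq <- paired_upregulation_fraction(rep(2, 10), rep(2, 10))
  expect_equal(eq$percent, 0)             # equal pairs are not "up"
  expect_error(paired_upregulation_fraction(1:3, 1:2), "mismatch")
  expect_error(paired_upregulation_fraction(c(1, -1), c(1, 1)), "positive")
})

test_that("chi-square reproduces the tissue-microarray worked examples", {
  m_stage <- matrix(c(117, 3, 121, 1), 2)   # rows M0/M1, cols low/high
  res <- chi_square_2x2(m_stage, correction = FALSE)
  expect_equal(round(res$p, 3), 0.305)
  # cross-check against the standard implementation
  expect_equal(res$statistic,
               unname(suppressWarnings(
                 chisq.test(m_stage, correct = FALSE)$statistic)))

  age <- matrix(c(23, 97, 24, 98), 2)
  res_y <- chi_square_2x2(age, correction = TRUE)
  expect_equal(res_y$statistic, 0)          # every |O-E| < 0.5, clamped
  expect_equal(res_y$p, 1.0)

  flat <- matrix(c(10, 10, 10, 10), 2)
  expect_equal(chi_square_2x2(flat)$statistic, 0)
  expect_equal(chi_square_2x2(flat)$p, 1)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("chi-square invariances hold and Yates is conservative", {
  set.seed(31)
  for (i in 1:20) {
    m <- matrix(rpois(4, 30) + 1, 2)
    p0 <- chi_square_2x2(m)$p
    expect_equal(chi_square_2x2(t(m))$p, p0)
    expect_equal(chi_square_2x2(m[2:1, 2:1])$p, p0)
    expect_gte(chi_square_2x2(m, correction = TRUE)$p, p0 - 1e-12)
    # agree with chisq.test on both variants
    expect_equal(chi_square_2x2(m)$statistic,
                 unname(chisq.test(m, correct = FALSE)$statistic))
    expect_equal(chi_square_2x2(m, TRUE)$statistic,
                 unname(suppressWarnings(chisq.test(m, correct = TRUE)$statistic)))
  }
})

test_that("Fisher exact matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(1, 2, 2))$p, 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))$p, 2 / 252)
  m_stage <- matrix(c(117, 3, 121, 1), 2)
  expect_equal(round(fisher_exact_2x2(m_stage)$p, 3), 0.368)

  set.seed(12)
  for (i in 1:20) {
    m <- matrix(rpois(4, 8), 2)
    if (sum(m) == 0) next
    oracle <- fisher_oracle(m)
    expect_equal(sum(oracle$probs), 1, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(m)$p, oracle$p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(m)$p,
                 fisher.test(m)$p.value, tolerance = 1e-7)
  }
})

test_that("Spearman correlation and its exact small-n p-value", {
  expect_equal(rank_correlation(1:10, (1:10)^3)$rho, 1)
  expect_equal(rank_correlation(1:10, -(1:10))$rho, -1)

  out <- rank_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(out$rho, 0.6)
  # exhaustive permutation oracle over all 4! orderings of y
  base <- c(2, 1, 4, 3)
  allp <- matrix(unlist(lapply(1:4, function(a)
    lapply(setdiff(1:4, a), function(b)
      lapply(setdiff(1:4, c(a, b)), function(cc)
        c(a, b, cc, setdiff(1:4, c(a, b, cc))))))), ncol = 4, byrow = TRUE)
  rho_all <- apply(allp, 1, function(idx) cor(1:4, base[idx]))
  expect_equal(out$p, mean(abs(rho_all) >= 0.6 - 1e-12))
  expect_equal(out$p, cor.test(c(1, 2, 3, 4), c(2, 1, 4, 3),
                               method = "spearman")$p.value,
               tolerance = 1e-9)

  big <- rank_correlation(1:50, (1:50) + rnorm(50, 0, 20))
  expect_true(big$p >= 0 && big$p <= 1)
  expect_error(rank_correlation(rep(1, 5), 1:5), "constant")
})

test_that("KM medians and log-rank follow the product-limit conventions", {
  expect_equal(km_median(1:5, rep(1, 5)), 3)  # S(3) = 0.4 <= 0.5

  time <- c(1:5, 1:5)
  event <- rep(1, 10)
  group <- rep(c("a", "b"), each = 5)
  out <- km_logrank(time, event, group)
  expect_equal(out$logrank$statistic, 0, tolerance = 1e-12)
  expect_equal(out$logrank$p, 1)
  expect_equal(unname(out$median), c(3, 3))

  # KM estimate is nonincreasing
  set.seed(3)
  fit <- survival::survfit(survival::Surv(rexp(30), rbinom(30, 1, .8)) ~ 1)
  expect_true(all(diff(fit$surv) <= 1e-12))

  expect_error(km_logrank(1:4, c(0, 0, 1, 1), c("a", "a", "b", "b")),
               "no events")
})
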