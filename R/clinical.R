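#' Dichotomize immunostaining scores
#'
#' Tissue-microarray staining intensity is scored 0 (none), 1 (weak),
#' 2 (moderate), 3 (strong); scores 0-1 are classified as low expression and
#' 2-3 as high.
#'
#' @param score integer vector over {0, 1, 2, 3}.
#' @return Character vector of `"low"` / `"high"`.
#' @export
dichotomize <- function(score) {
  if (any(!score %in% 0:3)) stop("staining scores must be in 0..3")
  ifelse(score >= 2, "high", "low")
}

#' Fraction of paired tumor/normal cases with up-regulation
#'
#' Counts pairs with `tumor / normal > min_ratio` (strict). With the default
#' ratio of 1, 31 up-regulated cases out of 40 pairs gives 77.5%.
#'
#' @param tumor,normal equal-length vectors of positive expression values.
#' @param min_ratio ratio above which a pair counts as up-regulated
#'   (default 1.0, strict `>`).
#' @return A list with `n_up`, `n_total`, `percent`.
#' @export
paired_upregulation_fraction <- function(tumor, normal, min_ratio = 1.0) {
  if (length(tumor) != length(normal)) stop("tumor/normal length mismatch")
  if (any(tumor <= 0) || any(normal <= 0)) {
    stop("expression values must be positive")
  }
  n_up <- sum(tumor / normal > min_ratio)
  list(n_up = n_up, n_total = length(tumor),
       percent = 100 * n_up / length(tumor))
}

as_2x2 <- function(t) {
  m <- as.matrix(t)
  if (!all(dim(m) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(m < 0) || any(m != floor(m))) stop("cells must be nonnegative integers")
  if (sum(m) == 0) stop("empty table")
  m
}

#' Chi-square test on a 2x2 contingency table
#'
#' Uncorrected Pearson statistic `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`,
#' or the Yates-corrected statistic with the per-cell term
#' `max(0, |O - E| - 0.5)^2 / E` (clamped at zero, so a table whose every
#' cell sits within 0.5 of expectation gives statistic 0 and p exactly 1).
#' The p-value is the upper tail of the chi-square distribution with 1 df.
#'
#' @param t 2x2 matrix/table (rows = covariate levels, cols = low/high).
#' @param correction apply Yates continuity correction (default FALSE).
#' @return A list: `method`, `statistic`, `p`, `df`.
#' @export
chi_square_2x2 <- function(t, correction = FALSE) {
  m <- as_2x2(t)
  margins_r <- rowSums(m)
  margins_c <- colSums(m)
  if (any(margins_r == 0) || any(margins_c == 0)) {
    stop("chi-square undefined: a margin is zero")
  }
  n <- sum(m)
  if (correction) {
    e <- outer(margins_r, margins_c) / n
    stat <- sum(pmax(0, abs(m - e) - 0.5)^2 / e)
    method <- "yates"
  } else {
    stat <- n * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
      prod(margins_r, margins_c)
    method <- "pearson"
  }
  list(method = method, statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE), df = 1L)
}

#' Fisher exact test on a 2x2 table (two-sided, point-probability rule)
#'
#' With margins fixed, the two-sided p-value is the sum of hypergeometric
#' point probabilities of all tables no more probable than the observed one
#' (the convention of common statistical software).
#'
#' @param t 2x2 matrix/table.
#' @return A list: `method`, `statistic` (the observed odds ratio estimate
#'   `ad/bc`, possibly Inf), `p`, `df` (NA).
#' @export
fisher_exact_2x2 <- function(t) {
  m <- as_2x2(t)
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0L, r1 + c1 - n)
  hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  list(method = "fisher", statistic = or, p = p, df = NA_integer_)
}

#' Spearman rank correlation
#'
#' Rho is the Pearson correlation of mid-ranks. For `n <= 8` the p-value is
#' computed by exhaustive enumeration over all permutations of one variable
#' (two-sided: fraction of permutations with `|rho| >= |rho_obs|`); for
#' larger n, the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` with
#' `n - 2` df is used.
#'
#' @param x,y equal-length numeric vectors, length >= 3.
#' @return A list with `rho` and `p`.
#' @export
rank_correlation <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) stop("need equal-length vectors, n >= 3")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("rank correlation undefined for a constant vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    perms <- permutations_of(n)
    rho_perm <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
  }
  list(rho = rho, p = p)
}

# All permutations of 1..n as a matrix (n! rows); n <= 8 keeps this small.
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Kaplan-Meier medians and log-rank test for two groups
#'
#' Product-limit survival estimate per group, with the median defined as the
#' smallest time at which the estimate drops to <= 0.5 (NA when never
#' reached), and the standard two-group log-rank test (1 df).
#'
#' @param time survival times (months, > 0).
#' @param event event indicator (1 = death, 0 = censored).
#' @param group two-level group labels (e.g. "low"/"high").
#' @return A list with `median` (named by group) and `logrank`, a list
#'   (`method`, `statistic`, `p`, `df`).
#' @export
km_logrank <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group),
            all(time > 0))
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("exactly two groups required")
  for (g in levels(group)) {
    if (sum(event[group == g]) < 1) stop("group ", g, " has no events")
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  med <- summary(fit)$table[, "median"]
  names(med) <- sub("^group=", "", rownames(summary(fit)$table))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- sd$chisq
  list(median = med,
       logrank = list(method = "logrank", statistic = stat,
                      p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                      df = 1L))
}

#' Kaplan-Meier median for a single sample
#'
#' @param time,event as in [km_logrank()].
#' @return The smallest time with survival <= 0.5 (NA if never reached).
#' @export
km_median <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  unname(summary(fit)$table["median"])
}
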