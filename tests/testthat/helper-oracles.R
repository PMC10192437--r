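# Independent oracles used across tests. These deliberately use naive
# character-by-character computation so they share no code path with the
# package implementation they check.

# Exact two-sample KS: statistic and p by enumerating every way to split the
# pooled values into the two groups (valid for small, tie-free inputs).
ks_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  grid <- sort(unique(pooled))
  d_of <- function(a, b) {
    fa <- vapply(grid, function(t) mean(a <= t), 0)
    fb <- vapply(grid, function(t) mean(b <= t), 0)
    max(abs(fa - fb))
  }
  d_obs <- d_of(x, y)
  splits <- utils::combn(m + n, m)
  d_all <- apply(splits, 2L, function(idx) d_of(pooled[idx], pooled[-idx]))
  list(D = d_obs, p = mean(d_all >= d_obs - 1e-12))
}

# Fisher two-sided p by full hypergeometric enumeration from log-factorials.
fisher_oracle <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  logp <- lchoose(c1, support) + lchoose(n - c1, r1 - support) - lchoose(n, r1)
  probs <- exp(logp)
  p_obs <- probs[support == m[1, 1]]
  list(p = min(1, sum(probs[probs <= p_obs * (1 + 1e-7)])), probs = probs)
}

# Naive quadratic seed-site scan: substring comparison at every offset.
naive_seed_scan <- function(utr, mir_id, mir) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) {
    v <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    paste0(comp[v], collapse = "")
  }
  utr <- chartr("U", "T", toupper(utr))
  mir <- chartr("U", "T", toupper(mir))
  core6 <- rc(substr(mir, 2, 7))
  m8b <- comp[[substr(mir, 8, 8)]]
  L <- nchar(utr)
  rows <- list()
  for (j1 in 1:(L - 5)) {            # 1-based core start
    if (substr(utr, j1, j1 + 5) != core6) next
    has_m8 <- j1 > 1 && substr(utr, j1 - 1, j1 - 1) == m8b
    has_a1 <- j1 + 6 <= L && substr(utr, j1 + 6, j1 + 6) == "A"
    j <- j1 - 1L                     # 0-based
    if (has_m8 && has_a1) {
      rows[[length(rows) + 1]] <- data.frame(
        mirna_id = mir_id, start = j - 1L, end = j + 7L, site_type = "8mer")
    } else if (has_m8) {
      rows[[length(rows) + 1]] <- data.frame(
        mirna_id = mir_id, start = j - 1L, end = j + 6L, site_type = "7mer-m8")
    } else if (has_a1) {
      rows[[length(rows) + 1]] <- data.frame(
        mirna_id = mir_id, start = j, end = j + 7L, site_type = "7mer-A1")
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna_id = character(0), start = integer(0),
                      end = integer(0), site_type = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

# Brute-force CpG island caller: per-window letter counting by substring,
# merge runs of passing windows, then the same maximal-passing trim rule
# computed naively.
brute_cpg_islands <- function(seq, window = 200L, min_len = 200L,
                              min_gc = 0.5, min_oe = 0.6) {
  seq <- toupper(seq)
  L <- nchar(seq)
  stats_of <- function(s, e) {       # 0-based half-open, naive counting
    sub <- substr(seq, s + 1, e)
    v <- strsplit(sub, "", fixed = TRUE)[[1]]
    n_c <- sum(v == "C"); n_g <- sum(v == "G")
    n_cpg <- 0
    if (length(v) >= 2) {
      for (i in 1:(length(v) - 1)) {
        if (v[i] == "C" && v[i + 1] == "G") n_cpg <- n_cpg + 1
      }
    }
    len <- e - s
    list(gc = (n_c + n_g) / len,
         oe = if (n_c * n_g == 0) 0 else n_cpg * len / (n_c * n_g))
  }
  passes <- function(s, e) {
    st <- stats_of(s, e)
    st$gc >= min_gc && st$oe >= min_oe
  }
  starts <- 0:(L - window)
  pass <- vapply(starts, function(s) passes(s, s + window), NA)
  out <- list()
  k <- 1
  while (k <= length(pass)) {
    if (!pass[k]) { k <- k + 1; next }
    j <- k
    while (j < length(pass) && pass[j + 1]) j <- j + 1
    idx <- k:j
    found <- NULL
    for (span in length(idx):1) {
      for (i in 1:(length(idx) - span + 1)) {
        s <- starts[idx[i]]
        e <- starts[idx[i + span - 1]] + window
        if (passes(s, e)) { found <- c(s, e); break }
      }
      if (!is.null(found)) break
    }
    if (!is.null(found) && found[2] - found[1] >= min_len) {
      out[[length(out) + 1]] <- data.frame(start = found[1], end = found[2])
    }
    k <- j + 1
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0)))
  do.call(rbind, out)
}

# Small screen fixture: library + truth + simulated two-sample counts.
small_screen <- function(n_genes = 50, n_ntc = 100, n_drivers = 5,
                         fitness = 0.2, reads = 5e5, seed = 1) {
  lib <- make_library(n_genes, 6, 0, 0, n_ntc, seed = 1)
  genes <- unique(lib$gene[lib$gene != "NTC"])
  drivers <- genes[seq_len(n_drivers)]
  truth <- stats::setNames(rep(fitness, n_drivers), drivers)
  cfg <- screen_sim_config(coverage = 200, reads_per_sample = reads,
                           seed = seed)
  sim <- simulate_screen(lib, truth, cfg)
  list(lib = lib, drivers = drivers, sim = sim, cfg = cfg)
}

# Random base string helper for sequence tests.
random_seq <- function(n, probs = c(0.25, 0.25, 0.25, 0.25)) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
         collapse = "")
}
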