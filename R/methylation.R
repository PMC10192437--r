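# Per-position letter indicator vectors and window sums via prefix sums.
window_stats <- function(seq_chr, window) {
  v <- strsplit(seq_chr, "", fixed = TRUE)[[1]]
  L <- length(v)
  is_c <- as.integer(v == "C")
  is_g <- as.integer(v == "G")
  is_cpg <- as.integer(v == "C" & c(v[-1], "") == "G")  # CpG start positions
  csum <- function(x) c(0, cumsum(x))
  list(L = L, c = csum(is_c), g = csum(is_g), cpg = csum(is_cpg))
}

# GC fraction and observed/expected CpG for 0-based half-open [start, end).
interval_gc_oe <- function(ps, start, end) {
  len <- end - start
  n_c <- ps$c[end + 1] - ps$c[start + 1]
  n_g <- ps$g[end + 1] - ps$g[start + 1]
  # CpG whose C lies in [start, end-1): fully inside the interval
  n_cpg <- if (len >= 2) ps$cpg[end] - ps$cpg[start + 1] else 0
  oe <- if (n_c * n_g == 0) 0 else n_cpg * len / (n_c * n_g)
  list(gc = (n_c + n_g) / len, oe = oe, n_cpg = n_cpg)
}

#' Predict CpG islands in a promoter sequence
#'
#' Gardiner-Garden-style sliding-window caller with MethPrimer-like defaults:
#' a window of width `window` slides one base at a time; windows with GC
#' fraction >= `min_gc` and observed/expected CpG >= `min_oe`
#' (`obs/exp = n_CpG * L / (n_C * n_G)`, defined as 0 when `n_C * n_G = 0`)
#' are merged when overlapping or adjacent. Each merged region is re-tested
#' on its whole extent; if it fails, it is trimmed to the longest
#' sub-interval spanned by a run of consecutive passing windows that passes
#' the whole-interval test (leftmost on ties). Regions shorter than
#' `min_len` are dropped. `N` bases count as non-C/non-G.
#'
#' @param seq promoter sequence over A/C/G/T/N.
#' @param window sliding-window width (default 200).
#' @param min_len minimum island length (default 200).
#' @param min_gc minimum GC fraction (default 0.50).
#' @param min_oe minimum observed/expected CpG ratio (default 0.60).
#' @return A data.frame of islands: `start`, `end` (0-based half-open),
#'   `length`, `gc_content`, `obs_exp_cpg`.
#' @export
find_cpg_islands <- function(seq, window = 200L, min_len = 200L,
                             min_gc = 0.50, min_oe = 0.60) {
  seq <- toupper(seq)
  if (!grepl("^[ACGTN]*$", seq)) stop("sequence must be over A/C/G/T/N")
  ps <- window_stats(seq, window)
  if (ps$L < window) stop("sequence shorter than the window")

  starts <- 0:(ps$L - window)  # 0-based window starts
  pass <- vapply(starts, function(s) {
    st <- interval_gc_oe(ps, s, s + window)
    st$gc >= min_gc && st$oe >= min_oe
  }, NA)

  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), gc_content = numeric(0),
                      obs_exp_cpg = numeric(0))
  if (!any(pass)) return(empty)

  runs <- rle(pass)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  out <- list()
  for (k in which(runs$values)) {
    win_idx <- run_start[k]:run_end[k]           # consecutive passing windows
    region <- trim_to_passing(ps, starts[win_idx], window, min_gc, min_oe)
    if (!is.null(region) && (region$end - region$start) >= min_len) {
      out[[length(out) + 1L]] <- data.frame(
        start = region$start, end = region$end,
        length = region$end - region$start,
        gc_content = region$gc, obs_exp_cpg = region$oe)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Largest whole-interval-passing union of consecutive passing windows,
# searched from the full merged span downward; leftmost on ties. A single
# passing window always passes, so the search terminates.
trim_to_passing <- function(ps, win_starts, window, min_gc, min_oe) {
  n <- length(win_starts)
  for (span in n:1) {
    for (i in 1:(n - span + 1)) {
      s <- win_starts[i]
      e <- win_starts[i + span - 1] + window
      st <- interval_gc_oe(ps, s, e)
      if (st$gc >= min_gc && st$oe >= min_oe) {
        return(list(start = s, end = e, gc = st$gc, oe = st$oe))
      }
    }
  }
  NULL
}

#' Per-CpG methylation fractions under a minimum-depth rule
#'
#' Sites with read coverage at least `min_depth` (inclusive; the screen used
#' depth >= 4) get `fraction = meth_count / coverage`; shallower sites are
#' flagged excluded with an undefined fraction.
#'
#' @param pileup data.frame with columns `chrom`, `pos` (0-based position of
#'   the forward-strand C), `coverage`, `meth_count`.
#' @param min_depth minimum coverage (default 4).
#' @return The pileup with `fraction` (NA when excluded) and logical
#'   `passing` columns added.
#' @export
site_methylation <- function(pileup, min_depth = 4L) {
  need <- c("chrom", "pos", "coverage", "meth_count")
  if (!all(need %in% names(pileup))) {
    stop("pileup needs columns: ", paste(need, collapse = ", "))
  }
  if (any(pileup$meth_count > pileup$coverage) ||
      any(pileup$meth_count < 0) || any(pileup$coverage < 0)) {
    stop("invalid pileup: need 0 <= meth_count <= coverage")
  }
  pileup$passing <- pileup$coverage >= min_depth
  pileup$fraction <- ifelse(pileup$passing,
                            pileup$meth_count / pileup$coverage, NA_real_)
  pileup
}

#' Region-level methylation, CpG density and GC content
#'
#' Summarizes a promoter region: CpG density is the count of CG dinucleotides
#' divided by region length, GC content the C+G fraction, both computed on
#' the forward strand of the underlying sequence; the mean methylation
#' fraction is taken over depth-passing sites inside the region and reported
#' as NA (not 0) when no site passes.
#'
#' @param region list or data.frame row with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param seq the region's DNA sequence (length `end - start`).
#' @param sites output of [site_methylation()]; only sites with
#'   `region$start <= pos < region$end` on `region$chrom` contribute.
#' @return A data.frame row: `chrom`, `start`, `end`, `n_sites_total`,
#'   `n_sites_passing`, `mean_meth_fraction`, `cpg_density`, `gc_content`.
#' @export
region_meth_stats <- function(region, seq, sites) {
  seq <- toupper(seq)
  len <- region$end - region$start
  if (len <= 0) stop("region must have start < end")
  if (nchar(seq) != len) stop("sequence does not cover the region")
  ps <- window_stats(seq, len)
  st <- interval_gc_oe(ps, 0, len)
  inside <- sites$chrom == region$chrom &
    sites$pos >= region$start & sites$pos < region$end
  sub <- sites[inside, , drop = FALSE]
  mean_frac <- if (any(sub$passing)) mean(sub$fraction[sub$passing]) else
    NA_real_
  data.frame(chrom = region$chrom, start = region$start, end = region$end,
             n_sites_total = nrow(sub),
             n_sites_passing = sum(sub$passing),
             mean_meth_fraction = mean_frac,
             cpg_density = st$n_cpg / len,
             gc_content = st$gc,
             stringsAsFactors = FALSE)
}

#' Classify a methylation difference between two regions
#'
#' `hyper_in_a` when `mean_a - mean_b >= delta`, `hypo_in_a` when
#' `<= -delta`, otherwise `unchanged`. The default delta of 0.25 is a
#' package convention for calling a region heavily hyper/hypomethylated.
#'
#' @param stats_a,stats_b rows from [region_meth_stats()] (or any objects
#'   with a defined `mean_meth_fraction`).
#' @param delta mean-difference threshold (default 0.25).
#' @return One of `"hyper_in_a"`, `"hypo_in_a"`, `"unchanged"`.
#' @export
compare_methylation <- function(stats_a, stats_b, delta = 0.25) {
  ma <- stats_a$mean_meth_fraction
  mb <- stats_b$mean_meth_fraction
  if (is.na(ma) || is.na(mb)) stop("undefined mean methylation fraction")
  d <- ma - mb
  if (d >= delta) "hyper_in_a" else if (d <= -delta) "hypo_in_a" else
    "unchanged"
}
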