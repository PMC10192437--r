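#' Simulate a bisulfite pileup over CpG sites
#'
#' Per site, read coverage is drawn from a negative binomial with the given
#' mean and dispersion, and the methylated read count from
#' `Binomial(coverage, true_meth_prob)`.
#'
#' @param chrom chromosome label.
#' @param site_positions sorted 0-based positions of the forward-strand C of
#'   each CpG.
#' @param true_meth_prob per-site methylation probability in `[0, 1]`
#'   (recycled).
#' @param mean_depth mean coverage (default 30).
#' @param depth_dispersion negative-binomial size parameter; larger is closer
#'   to Poisson (default 10).
#' @param seed integer seed.
#' @return A pileup data.frame: `chrom`, `pos`, `coverage`, `meth_count`,
#'   plus the generating `true_meth_prob`.
#' @export
simulate_bisulfite <- function(chrom, site_positions, true_meth_prob,
                               mean_depth = 30, depth_dispersion = 10,
                               seed = 1L) {
  stopifnot(all(diff(site_positions) > 0) || length(site_positions) <= 1,
            all(true_meth_prob >= 0), all(true_meth_prob <= 1),
            mean_depth > 0, depth_dispersion > 0)
  n <- length(site_positions)
  p <- rep_len(true_meth_prob, n)
  with_seed(seed, {
    coverage <- stats::rnbinom(n, size = depth_dispersion, mu = mean_depth)
    meth <- stats::rbinom(n, coverage, p)
    data.frame(chrom = chrom, pos = as.integer(site_positions),
               coverage = coverage, meth_count = meth,
               true_meth_prob = p, stringsAsFactors = FALSE)
  })
}

#' Simulate a differential-expression table with planted up-regulated genes
#'
#' Planted up-regulated genes get fold changes scattered tightly around
#' `true_fc` with very small p-values; the remaining (null) genes get fold
#' changes around 1 and uniform p-values. BH q-values are included.
#'
#' @param genes character vector of gene names.
#' @param up_genes subset of `genes` to plant as up-regulated.
#' @param true_fc fold change of planted genes (default 4).
#' @param up_p p-value assigned to planted genes (default 1e-6).
#' @param seed integer seed.
#' @return A DE data.frame: `gene`, `fold_change`, `p`, `q`.
#' @export
simulate_expression <- function(genes, up_genes = character(0), true_fc = 4,
                                up_p = 1e-6, seed = 1L) {
  if (!all(up_genes %in% genes)) stop("up_genes must be a subset of genes")
  stopifnot(true_fc > 0)
  n <- length(genes)
  up <- genes %in% up_genes
  with_seed(seed, {
    fc <- exp(stats::rnorm(n, mean = 0, sd = 0.1))
    fc[up] <- true_fc * exp(stats::rnorm(sum(up), 0, 0.05))
    p <- stats::runif(n)
    p[up] <- up_p
    data.frame(gene = genes, fold_change = fc, p = p,
               q = stats::p.adjust(p, method = "BH"),
               stringsAsFactors = FALSE)
  })
}

#' Build a 3'UTR with planted miRNA seed sites
#'
#' Generates a random background sequence free of any seed-core match for the
#' given miRNA, then plants `n_sites` sites of the requested class at random
#' non-overlapping positions. The construction is verified with an internal
#' scan: the returned UTR contains exactly the planted sites (type and
#' position) and nothing else for this miRNA.
#'
#' @param mirna_seq miRNA sequence (5'->3', >= 8 nt, RNA or DNA alphabet).
#' @param site_type one of `"8mer"`, `"7mer-m8"`, `"7mer-A1"`.
#' @param utr_len UTR length (default 1000).
#' @param n_sites number of sites to plant.
#' @param seed integer seed.
#' @return A list with `utr_seq` (DNA alphabet), and `sites`, a data.frame of
#'   the planted 0-based half-open intervals with their `site_type`.
#' @export
make_planted_utr <- function(mirna_seq, site_type = c("8mer", "7mer-m8", "7mer-A1"),
                             utr_len = 1000L, n_sites = 1L, seed = 1L) {
  site_type <- match.arg(site_type)
  mir <- as_dna_chr(mirna_seq)
  if (nchar(mir) < 8) stop("miRNA must be >= 8 nt")
  core7 <- revcomp_chr(substr(mir, 2, 8))  # UTR match to seed 2-8
  core6 <- revcomp_chr(substr(mir, 2, 7))
  site_str <- switch(site_type,
    "8mer" = paste0(core7, "A"),
    "7mer-m8" = core7,
    "7mer-A1" = paste0(core6, "A"))
  # for 7mer-m8, the base after the site must not be A (else it reads 8mer)
  site_len <- nchar(site_str)
  if (utr_len < n_sites * (site_len + 2L)) {
    stop("utr_len too small to plant ", n_sites, " sites")
  }

  with_seed(seed, {
    for (attempt in 1:200) {
      utr <- paste0(sample(DNA_BASES, utr_len, replace = TRUE), collapse = "")
      # candidate non-overlapping 0-based plant positions, leaving one base
      # of slack on each flank for the class-defining neighbours
      slots <- sort(sample(seq(1L, utr_len - site_len - 1L), n_sites))
      if (n_sites > 1 && any(diff(slots) < site_len + 2L)) next
      v <- strsplit(utr, "", fixed = TRUE)[[1]]
      for (s in slots) {
        v[(s + 1):(s + site_len)] <- strsplit(site_str, "", fixed = TRUE)[[1]]
        if (site_type == "7mer-m8" && v[s + site_len + 1] == "A") {
          v[s + site_len + 1] <- "C"
        }
        if (site_type == "7mer-A1") {
          m8_base <- revcomp_chr(substr(mir, 8, 8))
          if (v[s] == m8_base) v[s] <- setdiff(DNA_BASES, c(m8_base, "G"))[1]
        }
      }
      cand <- paste0(v, collapse = "")
      found <- seed_scan(cand, stats::setNames(mir, "planted"))
      want_start <- slots
      ok <- nrow(found) == n_sites &&
        all(found$site_type == site_type) &&
        all(sort(found$start) == sort(want_start))
      if (ok) {
        sites <- found[, c("start", "end", "site_type")]
        rownames(sites) <- NULL
        return(list(utr_seq = cand, sites = sites))
      }
    }
    stop("could not construct a UTR without spurious sites; ",
         "increase utr_len")
  })
}

#' Simulate a clinical cohort with tunable association and survival effect
#'
#' Emulates a tissue-microarray cohort: each patient gets a high/low tumor
#' expression flag (staining score 0-3, dichotomized 0/1 = low vs 2/3 =
#' high), one binary covariate associated with expression at a requested
#' odds ratio, and exponential survival with a hazard ratio between the
#' expression groups; censoring is independent uniform thinning.
#'
#' @param n_patients cohort size.
#' @param p_high probability of high expression (default 0.5).
#' @param odds_ratio covariate odds ratio, high vs low expression; the
#'   covariate prevalence in the low group is `p_cov_low` (default 0.5).
#' @param p_cov_low covariate prevalence in the low-expression group.
#' @param baseline_median median survival (months) of the low-expression
#'   group (default 31, exponential).
#' @param hazard_ratio hazard ratio of high vs low expression (default 1).
#' @param censor_frac expected fraction of censored patients in `[0, 1)`.
#' @param seed integer seed.
#' @return A data.frame: `patient`, `score` (0-3), `expression`
#'   ("low"/"high"), `covariate` (0/1), `time` (months), `event` (1 = death).
#' @export
simulate_cohort <- function(n_patients, p_high = 0.5, odds_ratio = 1,
                            p_cov_low = 0.5, baseline_median = 31,
                            hazard_ratio = 1, censor_frac = 0, seed = 1L) {
  stopifnot(n_patients > 0, p_high >= 0, p_high <= 1, odds_ratio > 0,
            baseline_median > 0, hazard_ratio > 0,
            censor_frac >= 0, censor_frac < 1)
  odds_low <- p_cov_low / (1 - p_cov_low)
  p_cov_high <- odds_ratio * odds_low / (1 + odds_ratio * odds_low)
  with_seed(seed, {
    high <- stats::runif(n_patients) < p_high
    score <- ifelse(high, sample(2:3, n_patients, replace = TRUE),
                    sample(0:1, n_patients, replace = TRUE))
    covariate <- as.integer(
      stats::runif(n_patients) < ifelse(high, p_cov_high, p_cov_low))
    rate <- log(2) / baseline_median * ifelse(high, hazard_ratio, 1)
    t_true <- stats::rexp(n_patients, rate)
    censored <- stats::runif(n_patients) < censor_frac
    time <- ifelse(censored, stats::runif(n_patients) * t_true, t_true)
    time <- pmax(time, 1e-6)
    data.frame(patient = sprintf("P%04d", seq_len(n_patients)),
               score = as.integer(score),
               expression = ifelse(high, "high", "low"),
               covariate = covariate,
               time = time,
               event = as.integer(!censored),
               stringsAsFactors = FALSE)
  })
}
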