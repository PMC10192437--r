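#' Normalize sgRNA counts to transcripts per million (TPM)
#'
#' Within each sample, `TPM = count / total clean-tag count * 1e6`, so every
#' sample column sums to one million. Normalization is scale-invariant:
#' multiplying a sample's counts by any positive constant leaves its TPM
#' column unchanged.
#'
#' @param tab [count_table()] or a numeric matrix with sample columns.
#' @return Numeric matrix of TPM values (guides x samples).
#' @export
tpm_normalize <- function(tab) {
  m <- if (inherits(tab, "count_table")) tab$counts else as.matrix(tab)
  totals <- colSums(m)
  zero <- totals <= 0
  if (any(zero)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(m)[zero], collapse = ", "))
  }
  sweep(m, 2L, totals, "/") * 1e6
}

#' Depletion thresholds
#'
#' An sgRNA is significantly depleted when its selected/input fold change is
#' strictly below `fc_thresh` and its p-value strictly below `p_thresh`
#' (defaults 0.5 and 0.005). A pseudocount (in TPM units) is added to both
#' numerator and denominator of the fold change to avoid division by zero
#' and shrink extreme ratios.
#'
#' @param fc_thresh fold-change threshold (default 0.5, strict `<`).
#' @param p_thresh p-value threshold (default 0.005, strict `<`).
#' @param pseudocount_tpm pseudocount in TPM (default 1).
#' @return A list of class `depletion_thresholds`.
#' @export
depletion_thresholds <- function(fc_thresh = 0.5, p_thresh = 0.005,
                                 pseudocount_tpm = 1.0) {
  stopifnot(fc_thresh > 0, p_thresh > 0, pseudocount_tpm >= 0)
  structure(list(fc_thresh = fc_thresh, p_thresh = p_thresh,
                 pseudocount_tpm = pseudocount_tpm),
            class = "depletion_thresholds")
}

#' Per-guide selected/input fold changes
#'
#' `fc = (tpm_selected + pseudocount) / (tpm_input + pseudocount)` and its
#' log2, per guide.
#'
#' @param tpm TPM matrix from [tpm_normalize()].
#' @param input_sample,selected_sample column names of the input and selected
#'   samples.
#' @param gene named character vector (sgRNA id -> gene), or a
#'   [count_table()] to take labels from.
#' @param thresholds [depletion_thresholds()].
#' @return A data.frame of depletion records: `sgrna_id`, `gene`,
#'   `tpm_input`, `tpm_selected`, `fc`, `log2fc` (p and depleted unset).
#' @export
sgrna_fold_changes <- function(tpm, input_sample, selected_sample, gene,
                               thresholds = depletion_thresholds()) {
  if (inherits(gene, "count_table")) gene <- gene$gene
  missing <- setdiff(c(input_sample, selected_sample), colnames(tpm))
  if (length(missing)) stop("unknown sample(s): ", paste(missing, collapse = ", "))
  pc <- thresholds$pseudocount_tpm
  ti <- tpm[, input_sample]
  ts <- tpm[, selected_sample]
  fc <- (ts + pc) / (ti + pc)
  data.frame(
    sgrna_id = rownames(tpm),
    gene = unname(gene[rownames(tpm)]),
    tpm_input = unname(ti),
    tpm_selected = unname(ts),
    fc = unname(fc),
    log2fc = log2(unname(fc)),
    p = NA_real_,
    depleted = NA,
    stringsAsFactors = FALSE
  )
}

#' Empirical-null depletion p-values
#'
#' The screen sequenced one sample per arm, so the per-guide Kolmogorov-
#' Smirnov test referenced for sgRNA-level significance cannot be formed as
#' stated (one observation per group); instead each guide gets a one-sided
#' empirical tail probability against a null distribution of log2 fold
#' changes: `p = (# null <= log2fc + 1) / (n_null + 1)`. The null is the
#' non-targeting controls when present (`null_source = "ntc"`), otherwise
#' all guides. A guide that itself belongs to the null set is scored
#' leave-one-out.
#'
#' @param records depletion records from [sgrna_fold_changes()].
#' @param null_source `"ntc"` (guides with gene "NTC") or `"all"`.
#' @return The records with the `p` column filled (values in (0, 1]).
#' @export
sgrna_depletion_pvalues <- function(records, null_source = c("ntc", "all")) {
  null_source <- match.arg(null_source)
  in_null <- if (null_source == "ntc") records$gene == "NTC" else
    rep(TRUE, nrow(records))
  if (!any(in_null)) stop("null source '", null_source, "' is empty")
  null_vals <- sort(records$log2fc[in_null])
  n_null <- length(null_vals)
  if (n_null < 50) {
    warning("only ", n_null, " guides in the null source; ",
            "empirical p-values will be coarse")
  }
  n_le <- findInterval(records$log2fc, null_vals)  # null <= value (sorted)
  self <- as.integer(in_null)  # leave-one-out when the guide is in the null
  records$p <- (n_le - self + 1) / (n_null - self + 1)
  records
}

#' Gene-level two-sample Kolmogorov-Smirnov test
#'
#' Compares the log2 fold changes of a gene's guides against those of all
#' other guides with a two-sample, two-sided KS test. The p-value is exact
#' when the combined sample size is at most 10 (and there are no ties),
#' asymptotic otherwise.
#'
#' @param records depletion records.
#' @param gene gene to test; needs >= 2 guides in and >= 2 outside the gene.
#' @return A list with `ks_D` and `ks_p`.
#' @export
gene_ks_test <- function(records, gene) {
  x <- records$log2fc[records$gene == gene]
  y <- records$log2fc[records$gene != gene]
  if (length(x) < 2 || length(y) < 2) {
    stop("gene_ks_test needs >= 2 guides inside and outside the gene")
  }
  exact <- (length(x) + length(y)) <= 10
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  list(ks_D = unname(kt$statistic), ks_p = min(1, unname(kt$p.value)))
}

#' Call significantly depleted sgRNAs
#'
#' A guide is depleted iff `fc < fc_thresh` and `p < p_thresh`, both strict.
#'
#' @param records depletion records with `fc` and `p` populated.
#' @param thresholds [depletion_thresholds()].
#' @return The records with the logical `depleted` column filled.
#' @export
call_depleted <- function(records, thresholds = depletion_thresholds()) {
  if (any(is.na(records$fc)) || any(is.na(records$p))) {
    stop("fc and p must be populated before calling depleted guides")
  }
  records$depleted <- records$fc < thresholds$fc_thresh &
    records$p < thresholds$p_thresh
  records
}

#' Aggregate depleted guides to genes
#'
#' One row per gene with at least `min_depleted` depleted guides, carrying
#' the guide tally, mean log2 fold change, and the gene-level KS test vs the
#' background of all other guides. Sorted by `n_depleted` (desc), then
#' `ks_p` (asc), then `mean_log2fc` (asc); NTC guides are never aggregated
#' into a gene row.
#'
#' @param records depletion records after [call_depleted()].
#' @param min_depleted minimum number of depleted guides (default 1).
#' @return A data.frame with columns `gene`, `n_sgrnas`, `n_depleted`,
#'   `mean_log2fc`, `ks_D`, `ks_p`.
#' @export
aggregate_genes <- function(records, min_depleted = 1L) {
  if (any(is.na(records$depleted))) stop("run call_depleted() first")
  keep <- records$gene != "NTC"
  genes <- unique(records$gene[keep])
  n_dep <- vapply(genes, function(g)
    sum(records$depleted[records$gene == g]), 0L)
  genes <- genes[n_dep >= min_depleted]
  if (length(genes) == 0) {
    return(data.frame(gene = character(0), n_sgrnas = integer(0),
                      n_depleted = integer(0), mean_log2fc = numeric(0),
                      ks_D = numeric(0), ks_p = numeric(0)))
  }
  rows <- lapply(genes, function(g) {
    sel <- records$gene == g
    ks <- gene_ks_test(records, g)
    data.frame(gene = g, n_sgrnas = sum(sel),
               n_depleted = sum(records$depleted[sel]),
               mean_log2fc = mean(records$log2fc[sel]),
               ks_D = ks$ks_D, ks_p = ks$ks_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_depleted, out$ks_p, out$mean_log2fc), ]
  rownames(out) <- NULL
  out
}

#' Cumulative sgRNA frequency (Lorenz curve), Gini and dropout fraction
#'
#' Library-diversity summary of one sample: guides are sorted by ascending
#' count and the cumulative fraction of reads is plotted against the
#' cumulative fraction of guides (a Lorenz curve). The Gini coefficient is
#' one minus twice the trapezoid area under the curve; a uniform library has
#' Gini 0, and a sample where one of n guides holds every read has Gini
#' 1 - 1/n. The fraction of guides with zero reads is reported alongside.
#'
#' @param tab [count_table()] or counts matrix.
#' @param sample sample (column) name.
#' @return A list with `curve` (data.frame `frac_guides`, `frac_reads`,
#'   including the (0,0) origin), `gini` and `zero_fraction`.
#' @export
cumulative_frequency <- function(tab, sample) {
  m <- if (inherits(tab, "count_table")) tab$counts else as.matrix(tab)
  if (!sample %in% colnames(m)) stop("unknown sample: ", sample)
  x <- sort(m[, sample])
  total <- sum(x)
  if (total == 0) stop("sample ", sample, " has zero total reads")
  n <- length(x)
  frac_guides <- c(0, seq_len(n) / n)
  frac_reads <- c(0, cumsum(x) / total)
  auc <- sum((frac_reads[-1] + frac_reads[-(n + 1)]) / 2 * diff(frac_guides))
  list(
    curve = data.frame(frac_guides = frac_guides, frac_reads = frac_reads),
    gini = 1 - 2 * auc,
    zero_fraction = mean(x == 0)
  )
}
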