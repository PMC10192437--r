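#' Select significantly up-regulated genes from a DE table
#'
#' A gene is up-regulated when its fold change (invasive/parental) is
#' strictly greater than `fc_min` and its BH-adjusted q-value strictly below
#' `q_max` (defaults 2.0 and 0.001). If the table carries only raw p-values,
#' Benjamini-Hochberg adjustment is applied first.
#'
#' @param de data.frame with columns `gene`, `fold_change`, and `p` and/or
#'   `q`.
#' @param fc_min fold-change threshold (strict `>`; default 2.0).
#' @param q_max FDR threshold (strict `<`; default 0.001).
#' @return Character vector of up-regulated gene names.
#' @export
de_upregulated <- function(de, fc_min = 2.0, q_max = 0.001) {
  if (nrow(de) == 0) stop("DE table is empty")
  if (!all(c("gene", "fold_change") %in% names(de))) {
    stop("DE table needs columns gene and fold_change")
  }
  if (is.null(de$q)) {
    if (is.null(de$p)) stop("DE table needs a p or q column")
    de$q <- stats::p.adjust(de$p, method = "BH")
  }
  de$gene[de$fold_change > fc_min & de$q < q_max]
}

#' Intersect screen hits with up-regulated genes
#'
#' The candidate shortlist is the intersection of genes called by the screen
#' (rows of a gene summary from [aggregate_genes()]) with the up-regulated
#' gene set from expression profiling. Candidates are ranked by `n_depleted`
#' (desc), then `ks_p` (asc), then DE fold change (desc), ties broken
#' lexicographically by gene name; the ranking criterion is a package
#' convention (configurable by reordering), not a published rule.
#'
#' @param gene_summaries gene summary table from [aggregate_genes()].
#' @param up_genes character vector of up-regulated genes, or the DE table
#'   itself (a data.frame with `gene` and `fold_change`), in which case fold
#'   changes are carried into the ranking.
#' @param de optional DE table used to attach `fold_change`/`q` columns when
#'   `up_genes` is a plain character vector.
#' @return A data.frame of candidates with screen fields, DE fields where
#'   available, and a gapless `rank` column.
#' @export
overlap_candidates <- function(gene_summaries, up_genes, de = NULL) {
  if (is.data.frame(up_genes)) {
    de <- up_genes
    up_genes <- de$gene
  }
  hit <- gene_summaries[gene_summaries$gene %in% up_genes, , drop = FALSE]
  hit$fold_change <- rep(NA_real_, nrow(hit))
  hit$q <- rep(NA_real_, nrow(hit))
  if (!is.null(de)) {
    idx <- match(hit$gene, de$gene)
    hit$fold_change <- de$fold_change[idx]
    if (!is.null(de$q)) hit$q <- de$q[idx]
  }
  fc_key <- ifelse(is.na(hit$fold_change), -Inf, hit$fold_change)
  ord <- order(-hit$n_depleted, hit$ks_p, -fc_key, hit$gene)
  hit <- hit[ord, , drop = FALSE]
  hit$rank <- seq_len(nrow(hit))
  rownames(hit) <- NULL
  hit
}

#' Scan a 3'UTR for miRNA seed-match sites
#'
#' TargetScan-style canonical site classes, anchored at each occurrence of
#' the 6-nt match to miRNA seed positions 2-7 (the reverse complement of the
#' seed in the UTR; G:U wobble is not accepted):
#' * `8mer`: seed 2-8 match plus `A` opposite miRNA position 1 (8-nt site);
#' * `7mer-m8`: seed 2-8 match alone (7-nt site);
#' * `7mer-A1`: seed 2-7 match plus the `A` (7-nt site).
#' Each core register yields at most one site of the strongest class;
#' overlapping registers are all reported. U and T are equivalent on input.
#'
#' @param utr_seq UTR sequence (character, RNA or DNA alphabet).
#' @param mirnas named character vector (miRNA id -> sequence, 5'->3', at
#'   least 8 nt each).
#' @return A data.frame with columns `mirna_id`, `start`, `end` (0-based,
#'   half-open UTR coordinates) and `site_type`.
#' @export
seed_scan <- function(utr_seq, mirnas) {
  utr <- as_dna_chr(utr_seq)
  if (!grepl("^[ACGTN]*$", utr)) stop("degenerate UTR sequence")
  if (is.null(names(mirnas)) || any(names(mirnas) == "")) {
    stop("mirnas must be a named vector")
  }
  out <- list()
  utr_dna <- Biostrings::DNAString(utr)
  L <- nchar(utr)
  for (id in names(mirnas)) {
    mir <- as_dna_chr(mirnas[[id]])
    if (nchar(mir) < 8) stop("miRNA ", id, " shorter than 8 nt")
    core <- revcomp_chr(substr(mir, 2, 7))          # matches positions 2-7
    m8_base <- revcomp_chr(substr(mir, 8, 8))       # UTR base pairing pos 8
    starts <- Biostrings::start(
      Biostrings::matchPattern(core, utr_dna, fixed = TRUE)) - 1L  # 0-based
    for (j in starts) {
      has_m8 <- j >= 1 && substr(utr, j, j) == m8_base
      has_a1 <- (j + 6 < L) && substr(utr, j + 7, j + 7) == "A"
      if (has_m8 && has_a1) {
        out[[length(out) + 1L]] <- data.frame(
          mirna_id = id, start = j - 1L, end = j + 7L, site_type = "8mer")
      } else if (has_m8) {
        out[[length(out) + 1L]] <- data.frame(
          mirna_id = id, start = j - 1L, end = j + 6L, site_type = "7mer-m8")
      } else if (has_a1) {
        out[[length(out) + 1L]] <- data.frame(
          mirna_id = id, start = j, end = j + 7L, site_type = "7mer-A1")
      }
    }
  }
  if (!length(out)) {
    return(data.frame(mirna_id = character(0), start = integer(0),
                      end = integer(0), site_type = character(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$mirna_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Rank candidate miRNAs targeting a UTR
#'
#' Keeps miRNAs that have at least one seed site in the UTR and are in the
#' down-regulated set, ranked by best site class (`8mer` > `7mer-m8` >
#' `7mer-A1`), then total site count (desc), then id.
#'
#' @param sites site table from [seed_scan()].
#' @param down_mirnas character vector of down-regulated miRNA ids.
#' @return A data.frame with `mirna_id`, `best_class`, `n_sites`, `rank`.
#' @export
mirna_candidates <- function(sites, down_mirnas) {
  class_rank <- c("8mer" = 1L, "7mer-m8" = 2L, "7mer-A1" = 3L)
  keep <- sites[sites$mirna_id %in% down_mirnas, , drop = FALSE]
  if (nrow(keep) == 0) {
    return(data.frame(mirna_id = character(0), best_class = character(0),
                      n_sites = integer(0), rank = integer(0)))
  }
  ids <- unique(keep$mirna_id)
  best <- vapply(ids, function(m)
    min(class_rank[keep$site_type[keep$mirna_id == m]]), 0L)
  n_sites <- vapply(ids, function(m) sum(keep$mirna_id == m), 0L)
  ord <- order(best, -n_sites, ids)
  data.frame(mirna_id = ids[ord],
             best_class = names(class_rank)[best[ord]],
             n_sites = unname(n_sites[ord]),
             rank = seq_along(ord),
             stringsAsFactors = FALSE)
}
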