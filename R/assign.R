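#' Assign clean reads to library sgRNAs
#'
#' Each read is scanned against every library spacer at every offset on the
#' forward strand (and optionally the reverse complement), tolerating up to
#' `max_mismatch` Hamming mismatches; `N` bases never match. A read counting
#' toward a guide must match exactly one distinct guide: reads matching none
#' are tallied as unassigned, reads matching more than one distinct guide as
#' ambiguous (discarded, not fractionally assigned). The default of one
#' mismatch mirrors a word-size-18 mapping regime on 20-nt spacers; full
#' local alignment is deliberately not performed.
#'
#' @param reads clean [fastq_reads()] (run [qc_filter()] first).
#' @param library guide library; duplicate spacers are rejected.
#' @param max_mismatch 0, 1 or 2 (default 1).
#' @param sample sample name for the resulting single-column table.
#' @param revcomp also match the reverse complement of each read (for real
#'   data; the simulator emits forward reads). Default FALSE.
#' @return A single-sample [count_table()] with unassigned/ambiguous counters.
#' @export
assign_sgrnas <- function(reads, library, max_mismatch = 1L,
                          sample = "sample", revcomp = FALSE) {
  stopifnot(inherits(reads, "fastq_reads"))
  validate_library(library)
  if (nrow(library) == 0) stop("library is empty")
  if (!max_mismatch %in% 0:2) stop("max_mismatch must be 0, 1 or 2")

  hits <- .match_spacers(reads$bases, library$spacer, as.integer(max_mismatch))
  if (revcomp && length(reads)) {
    rc_hits <- .match_spacers(revcomp_chr(reads$bases), library$spacer,
                              as.integer(max_mismatch))
    hits <- combine_strand_hits(hits, rc_hits)
  }

  counts <- tabulate(hits[hits > 0], nbins = nrow(library))
  m <- matrix(as.integer(counts), ncol = 1,
              dimnames = list(library$sgrna_id, sample))
  count_table(
    m, stats::setNames(library$gene, library$sgrna_id),
    unassigned = stats::setNames(sum(hits == 0), sample),
    ambiguous = stats::setNames(sum(hits == -1), sample)
  )
}

# Merge forward/reverse hit codes: a guide found on either strand counts
# once; distinct guides across strands make the read ambiguous.
combine_strand_hits <- function(fwd, rev) {
  out <- fwd
  out[fwd == 0] <- rev[fwd == 0]
  both <- fwd > 0 & rev > 0 & fwd != rev
  out[both | fwd == -1 | rev == -1] <- -1L
  out
}

#' Quantify screen FASTQ files into a count table
#'
#' End-to-end read processing for a screen: each per-sample FASTQ is QC
#' filtered with [qc_filter()] and the clean reads assigned to guides with
#' [assign_sgrnas()]; per-sample tables are bound into one [count_table()].
#'
#' @param fastq_paths named character vector, sample name -> FASTQ path.
#' @param library guide library.
#' @param rules [qc_rules()].
#' @param max_mismatch passed to [assign_sgrnas()].
#' @param revcomp passed to [assign_sgrnas()].
#' @return A list with `counts` (a [count_table()]) and `qc`, a data.frame of
#'   per-sample QC report rows.
#' @export
quantify_fastq <- function(fastq_paths, library, rules = qc_rules(),
                           max_mismatch = 1L, revcomp = FALSE) {
  stopifnot(length(fastq_paths) > 0, !is.null(names(fastq_paths)))
  tabs <- list()
  qc <- list()
  for (sample in names(fastq_paths)) {
    flt <- qc_filter(read_fastq(fastq_paths[[sample]]), rules)
    qc[[sample]] <- cbind(sample = sample, flt$report)
    tabs[[sample]] <- assign_sgrnas(flt$reads, library,
                                    max_mismatch = max_mismatch,
                                    sample = sample, revcomp = revcomp)
  }
  m <- do.call(cbind, lapply(tabs, function(t) t$counts))
  colnames(m) <- names(fastq_paths)
  tab <- count_table(
    m, tabs[[1]]$gene,
    unassigned = vapply(tabs, function(t) t$unassigned, 0),
    ambiguous = vapply(tabs, function(t) t$ambiguous, 0)
  )
  list(counts = tab, qc = do.call(rbind, qc))
}
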