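# Fixed amplicon layout for simulated screen reads: 10-nt 5' vector context,
# the 20-nt spacer, then 3' vector context. The true amplicon structure of
# the assay is not modelled; only the embedded spacer matters downstream.
READ_CONTEXT_5P <- "GTGGAAAGGA"
READ_CONTEXT_3P <- "GTTTTAGAGC"

#' Emit simulated FASTQ reads for a count table
#'
#' Every counted guide is emitted as that many reads embedding its spacer at
#' a fixed offset (10 nt) inside constant vector context, at uniformly high
#' base quality (Q40), with optional per-base substitution errors. Contaminant
#' reads are then appended per the configured fractions of total emitted
#' reads, in three mutually exclusive classes matched to the QC rules:
#' N-rich reads (half the bases N), low-quality reads (60% of bases at Q10)
#' and adapter-bearing reads. Read ids encode the ground truth
#' (`sample:sgrna_id:serial` or `sample:contam_<class>:serial`) so assignment
#' can be audited.
#'
#' @param tab [count_table()] whose guides are all in `library`.
#' @param library guide library.
#' @param config [screen_sim_config()]; uses the contamination fractions,
#'   adapter, `seq_error_rate` and `seed`.
#' @param dir output directory; one `<sample>.fastq` per sample.
#' @return Named character vector of written FASTQ paths.
#' @export
emit_fastq <- function(tab, library, config = screen_sim_config(), dir) {
  stopifnot(inherits(tab, "count_table"))
  validate_library(library)
  if (!all(rownames(tab$counts) %in% library$sgrna_id)) {
    stop("count table contains guides absent from the library")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in seq_len(ncol(tab$counts))) {
    sample <- colnames(tab$counts)[s]
    reads <- with_seed(config$seed + s, build_sample_reads(
      counts = tab$counts[, s], library = library, config = config,
      sample = sample))
    path <- file.path(dir, paste0(sample, ".fastq"))
    write_fastq(reads, path)
    paths[sample] <- path
  }
  paths
}

# Assemble clean + contaminant reads for one sample (caller seeds the RNG).
build_sample_reads <- function(counts, library, config, sample) {
  spacer <- library$spacer[match(names(counts), library$sgrna_id)]
  reps <- rep.int(seq_along(counts), counts)
  bases <- paste0(READ_CONTEXT_5P, spacer[reps], READ_CONTEXT_3P)
  ids <- paste0(sample, ":", names(counts)[reps], ":", seq_along(reps))
  width <- nchar(READ_CONTEXT_5P) + 20L + nchar(READ_CONTEXT_3P)
  if (config$seq_error_rate > 0 && length(bases)) {
    bases <- apply_seq_errors(bases, config$seq_error_rate)
  }
  hi_q <- int_to_phred(rep(40L, width))
  quals <- rep(hi_q, length(bases))

  n_clean <- length(bases)
  f_sum <- config$frac_n_contam + config$frac_lowq_contam +
    config$frac_adapter_contam
  if (f_sum > 0 && n_clean > 0) {
    total <- round(n_clean / (1 - f_sum))
    n_n <- stats::rbinom(1, total, config$frac_n_contam)
    n_lq <- stats::rbinom(1, total, config$frac_lowq_contam)
    n_ad <- stats::rbinom(1, total, config$frac_adapter_contam)
    contam <- make_contaminants(n_n, n_lq, n_ad, width, config$adapter, sample)
    bases <- c(bases, contam$bases)
    quals <- c(quals, contam$quals)
    ids <- c(ids, contam$id)
  }
  fastq_reads(ids, bases, quals)
}

apply_seq_errors <- function(bases, rate) {
  vapply(bases, function(b) {
    v <- strsplit(b, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(v)) < rate)
    for (i in hit) v[i] <- sample(setdiff(DNA_BASES, v[i]), 1)
    paste0(v, collapse = "")
  }, "", USE.NAMES = FALSE)
}

random_bases <- function(n, width) {
  if (n == 0) return(character(0))
  m <- matrix(sample(DNA_BASES, n * width, replace = TRUE), nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

make_contaminants <- function(n_n, n_lq, n_ad, width, adapter, sample) {
  hi_q <- int_to_phred(rep(40L, width))

  # N-rich: half of the positions are N (>= the 10% removal threshold).
  b_n <- random_bases(n_n, width)
  if (n_n > 0) {
    n_pos <- ceiling(width / 2)
    b_n <- vapply(b_n, function(b) {
      v <- strsplit(b, "", fixed = TRUE)[[1]]
      v[sample.int(width, n_pos)] <- "N"
      paste0(v, collapse = "")
    }, "", USE.NAMES = FALSE)
  }

  # Low-quality: 60% of the positions at Q10 (> the 40%-at-Q<=20 threshold).
  b_lq <- random_bases(n_lq, width)
  q_lq <- vapply(seq_len(n_lq), function(i) {
    q <- rep(40L, width)
    q[sample.int(width, ceiling(0.6 * width))] <- 10L
    int_to_phred(q)
  }, "", USE.NAMES = FALSE)

  # Adapter-bearing: adapter embedded at a random offset.
  b_ad <- random_bases(n_ad, width)
  if (n_ad > 0) {
    alen <- nchar(adapter)
    if (alen > width) stop("adapter longer than read width")
    b_ad <- vapply(b_ad, function(b) {
      at <- sample.int(width - alen + 1L, 1L)
      paste0(substr(b, 1, at - 1L), adapter, substr(b, at + alen, width))
    }, "", USE.NAMES = FALSE)
  }

  list(
    id = c(sprintf("%s:contam_n:%d", sample, seq_len(n_n)),
           sprintf("%s:contam_lowq:%d", sample, seq_len(n_lq)),
           sprintf("%s:contam_adapter:%d", sample, seq_len(n_ad))),
    bases = c(b_n, b_lq, b_ad),
    quals = c(rep(hi_q, n_n), q_lq, rep(hi_q, n_ad))
  )
}
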