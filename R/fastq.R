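#' In-memory FASTQ read set
#'
#' Lightweight container for Sanger Phred+33 reads: ids, base strings over
#' A/C/G/T/N, and quality strings of equal length.
#'
#' @param id character vector of read ids.
#' @param bases character vector of base strings.
#' @param quals character vector of Phred+33 quality strings.
#' @return An object of class `fastq_reads`.
#' @export
fastq_reads <- function(id, bases, quals) {
  if (length(id) != length(bases) || length(bases) != length(quals)) {
    stop("id, bases and quals must have equal length")
  }
  if (any(nchar(bases) != nchar(quals))) {
    stop("bases and quals must have matching lengths per read")
  }
  structure(list(id = as.character(id), bases = toupper(as.character(bases)),
                 quals = as.character(quals)),
            class = "fastq_reads")
}

#' @export
length.fastq_reads <- function(x) length(x$id)

#' @export
print.fastq_reads <- function(x, ...) {
  cat("fastq_reads:", length(x), "reads\n")
  invisible(x)
}

subset_reads <- function(x, i) fastq_reads(x$id[i], x$bases[i], x$quals[i])

#' Read / write FASTQ (4-line records, Phred+33)
#'
#' Thin wrappers around Biostrings FASTQ I/O returning/accepting
#' [fastq_reads()].
#'
#' @param path FASTQ file path (plain or gzip for reading).
#' @param reads a `fastq_reads` object.
#' @return `read_fastq` returns a `fastq_reads` object.
#' @export
read_fastq <- function(path) {
  # the Biostrings reader warns about dropping its own metadata columns
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  fastq_reads(names(x), as.character(x),
              as.character(Biostrings::quality(x)))
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "fastq_reads"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(reads)) {
    writeLines(paste0("@", reads$id, "\n", reads$bases, "\n+\n", reads$quals),
               con)
  }
  invisible(path)
}

phred_to_int <- function(quals) {
  lapply(quals, function(q) utf8ToInt(q) - 33L)
}

int_to_phred <- function(q) intToUtf8(q + 33L)

#' QC filtering rules for raw screen reads
#'
#' The three stringent filtering standards applied to raw reads before guide
#' assignment: (1) drop reads with >= `max_n_frac` unidentified nucleotides
#' (N); (2) drop reads with more than `max_lowq_frac` of bases at Phred
#' quality <= `lowq_threshold`; (3) drop reads matching the barcode adapter.
#' The N rule is boundary-inclusive (>=) and the low-quality rule strict (>).
#'
#' @param max_n_frac maximum tolerated N fraction (default 0.10, inclusive).
#' @param lowq_threshold Phred score at or below which a base counts as
#'   low quality (default 20).
#' @param max_lowq_frac maximum tolerated fraction of low-quality bases
#'   (default 0.40, exclusive).
#' @param adapter adapter sequence; a read is dropped if the adapter or its
#'   reverse complement occurs as an exact substring.
#' @return A list of class `qc_rules`.
#' @export
qc_rules <- function(max_n_frac = 0.10, lowq_threshold = 20L,
                     max_lowq_frac = 0.40, adapter = "AGATCGGAAGAGC") {
  stopifnot(max_n_frac >= 0, max_n_frac <= 1,
            max_lowq_frac >= 0, max_lowq_frac <= 1,
            lowq_threshold >= 0)
  structure(list(max_n_frac = max_n_frac,
                 lowq_threshold = as.integer(lowq_threshold),
                 max_lowq_frac = max_lowq_frac, adapter = adapter),
            class = "qc_rules")
}

#' Filter raw reads to high-quality clean reads
#'
#' Applies the three filtering standards in [qc_rules()] in order (N content,
#' low-quality fraction, adapter). A read failing several rules is attributed
#' to the first one in that order.
#'
#' @param reads [fastq_reads()].
#' @param rules [qc_rules()].
#' @return A list with `reads` (the surviving clean reads) and `report`, a
#'   data.frame of reads in/removed per rule/kept.
#' @export
qc_filter <- function(reads, rules = qc_rules()) {
  stopifnot(inherits(reads, "fastq_reads"))
  if (any(nchar(reads$bases) != nchar(reads$quals))) {
    stop("bases/quals length mismatch in read set")
  }
  n <- length(reads)
  if (n == 0) {
    rep0 <- data.frame(total = 0L, removed_n = 0L, removed_lowq = 0L,
                       removed_adapter = 0L, kept = 0L)
    return(list(reads = reads, report = rep0))
  }
  width <- nchar(reads$bases)
  dna <- Biostrings::DNAStringSet(reads$bases)
  n_frac <- as.vector(Biostrings::letterFrequency(dna, "N")) / width
  fail_n <- n_frac >= rules$max_n_frac

  qint <- phred_to_int(reads$quals)
  lowq_frac <- vapply(qint, function(q) mean(q <= rules$lowq_threshold), 0)
  fail_lowq <- !fail_n & lowq_frac > rules$max_lowq_frac

  has_adapter <-
    Biostrings::vcountPattern(rules$adapter, dna, fixed = TRUE) > 0 |
    Biostrings::vcountPattern(revcomp_chr(rules$adapter), dna, fixed = TRUE) > 0
  fail_adapter <- !fail_n & !fail_lowq & has_adapter

  keep <- !(fail_n | fail_lowq | fail_adapter)
  report <- data.frame(
    total = n,
    removed_n = sum(fail_n),
    removed_lowq = sum(fail_lowq),
    removed_adapter = sum(fail_adapter),
    kept = sum(keep)
  )
  list(reads = subset_reads(reads, keep), report = report)
}
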