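#' sgRNA count table container
#'
#' Holds an sgRNA x sample matrix of nonnegative integer read counts together
#' with the gene label of each guide and, per sample, the number of clean
#' reads that could not be assigned (no matching spacer) or were ambiguous
#' (matched more than one guide). The partition invariant
#' `assigned + unassigned + ambiguous == clean reads in` holds per sample.
#'
#' @param counts integer matrix, rownames = sgRNA ids, colnames = samples.
#' @param gene character vector of gene labels, one per guide (named by
#'   sgRNA id or in row order).
#' @param unassigned,ambiguous named numeric vectors, one entry per sample
#'   (default all zero).
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, gene,
                        unassigned = NULL, ambiguous = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) > 0 && is.null(rownames(counts))) {
    stop("counts must have sgRNA ids as rownames")
  }
  if (is.null(colnames(counts))) stop("counts must have sample names as colnames")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(counts != floor(counts))) stop("counts must be integers")
  if (!is.null(names(gene)) && nrow(counts) > 0) gene <- gene[rownames(counts)]
  if (length(gene) != nrow(counts)) stop("one gene label per guide required")
  zero <- stats::setNames(numeric(ncol(counts)), colnames(counts))
  unassigned <- if (is.null(unassigned)) zero else unassigned[colnames(counts)]
  ambiguous <- if (is.null(ambiguous)) zero else ambiguous[colnames(counts)]
  structure(
    list(counts = counts,
         gene = stats::setNames(as.character(gene), rownames(counts)),
         unassigned = unassigned, ambiguous = ambiguous),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "guides x", ncol(x$counts), "samples\n")
  cat("samples:", paste(colnames(x$counts), collapse = ", "), "\n")
  cat("totals:", paste(colSums(x$counts), collapse = ", "), "\n")
  cat("unassigned:", paste(x$unassigned, collapse = ", "),
      " ambiguous:", paste(x$ambiguous, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Write / read an sgRNA count table as TSV
#'
#' The on-disk format is a TSV with columns `sgrna_id`, `gene`, then one
#' column per sample, preceded by comment lines carrying the per-sample
#' unassigned/ambiguous counters so the round trip is lossless:
#' `read_counts(write_counts(x, f)) == x`. Column order is fixed, making the
#' output byte-stable for a given table.
#'
#' @param tab `count_table`.
#' @param path file path.
#' @return `read_counts` returns a `count_table`.
#' @export
write_counts <- function(tab, path) {
  stopifnot(inherits(tab, "count_table"))
  con <- file(path, "w")
  on.exit(close(con))
  fmt_num <- function(v) format(v, scientific = FALSE, trim = TRUE)
  writeLines(paste0("# unassigned\t",
                    paste(colnames(tab$counts), fmt_num(tab$unassigned),
                          sep = "=", collapse = "\t")), con)
  writeLines(paste0("# ambiguous\t",
                    paste(colnames(tab$counts), fmt_num(tab$ambiguous),
                          sep = "=", collapse = "\t")), con)
  df <- data.frame(sgrna_id = rownames(tab$counts) %||% character(0),
                   gene = unname(tab$gene),
                   tab$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  hdr <- readLines(path, n = 2L)
  parse_counter <- function(line, tag) {
    if (!startsWith(line, paste0("# ", tag))) {
      stop("malformed counts file: missing '# ", tag, "' header line")
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]][-1]
    if (length(fields) == 0) return(numeric(0))
    kv <- strsplit(fields, "=", fixed = TRUE)
    stats::setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                    vapply(kv, `[`, "", 1L))
  }
  unassigned <- parse_counter(hdr[1], "unassigned")
  ambiguous <- parse_counter(hdr[2], "ambiguous")
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sgrna_id", "gene") %in% names(df))) {
    stop("malformed counts file: need sgrna_id and gene columns")
  }
  samples <- setdiff(names(df), c("sgrna_id", "gene"))
  m <- as.matrix(df[, samples, drop = FALSE])
  if (any(is.na(m))) stop("malformed counts file: non-numeric entries")
  if (any(m < 0)) stop("malformed counts file: negative counts")
  rownames(m) <- df$sgrna_id
  count_table(m, stats::setNames(df$gene, df$sgrna_id),
              unassigned = unassigned, ambiguous = ambiguous)
}
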