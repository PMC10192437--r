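#' Generate a pooled CRISPR knockout library design
#'
#' Builds a GeCKO-style guide catalog: protein-coding genes with a fixed
#' number of sgRNAs each, miRNA genes with their own guide multiplicity, and
#' non-targeting controls (NTCs). Spacers are unique random 20-mers over
#' A/C/G/T; sgRNA ids are unique. The full GeCKOv2 design corresponds to
#' 19,050 coding genes at 6 guides/gene plus 1,864 miRNAs at 4 guides/miRNA;
#' simulations in this package use scaled-down libraries of the same shape.
#'
#' @param n_genes number of protein-coding genes.
#' @param sgrnas_per_gene guides per protein-coding gene.
#' @param n_mirna number of miRNA genes.
#' @param sgrnas_per_mirna guides per miRNA gene.
#' @param n_ntc number of non-targeting control guides (gene label "NTC").
#' @param seed integer seed; the same seed reproduces the same library.
#' @return A `data.frame` with columns `sgrna_id`, `gene`, `target_class`
#'   (one of `protein_coding`, `mirna`, `ntc`) and `spacer` (20-nt string).
#' @export
make_library <- function(n_genes, sgrnas_per_gene, n_mirna, sgrnas_per_mirna,
                         n_ntc, seed) {
  counts <- c(n_genes, sgrnas_per_gene, n_mirna, sgrnas_per_mirna, n_ntc)
  stopifnot(all(counts >= 0), all(counts == floor(counts)))
  n_total <- n_genes * sgrnas_per_gene + n_mirna * sgrnas_per_mirna + n_ntc
  if (n_total > 4^20) {
    stop("requested ", n_total, " unique spacers; only 4^20 distinct 20-mers exist")
  }
  gene <- c(
    rep(sprintf("GENE%04d", seq_len(n_genes)), each = sgrnas_per_gene),
    rep(sprintf("MIR%04d", seq_len(n_mirna)), each = sgrnas_per_mirna),
    rep("NTC", n_ntc)
  )
  target_class <- c(
    rep("protein_coding", n_genes * sgrnas_per_gene),
    rep("mirna", n_mirna * sgrnas_per_mirna),
    rep("ntc", n_ntc)
  )
  spacer <- with_seed(seed, draw_unique_spacers(n_total))
  lib <- data.frame(
    sgrna_id = sprintf("sg_%06d", seq_len(n_total)),
    gene = gene,
    target_class = target_class,
    spacer = spacer,
    stringsAsFactors = FALSE
  )
  validate_library(lib)
  lib
}

# Rejection-sample unique random 20-mers.
draw_unique_spacers <- function(n, width = 20L) {
  if (n == 0L) return(character(0))
  out <- character(0)
  attempts <- 0L
  while (length(out) < n) {
    need <- n - length(out)
    mat <- matrix(sample(DNA_BASES, need * width, replace = TRUE), nrow = need)
    cand <- apply(mat, 1L, paste0, collapse = "")
    out <- unique(c(out, cand))
    attempts <- attempts + 1L
    if (attempts > 100L) stop("could not draw ", n, " unique spacers")
  }
  out[seq_len(n)]
}

#' Validate a guide library table
#'
#' Checks the library invariants: unique sgRNA ids, unique 20-nt spacers over
#' A/C/G/T, and NTC records labelled with gene "NTC".
#'
#' @param lib library `data.frame` as returned by [make_library()].
#' @return The library, invisibly, if valid; otherwise an error.
#' @export
validate_library <- function(lib) {
  need <- c("sgrna_id", "gene", "target_class", "spacer")
  if (!all(need %in% names(lib))) {
    stop("library must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(lib$sgrna_id)) stop("duplicate sgrna_id in library")
  if (anyDuplicated(lib$spacer)) stop("duplicate spacers in library")
  if (nrow(lib) > 0) {
    if (!all(nchar(lib$spacer) == 20L)) stop("all spacers must be 20 nt")
    if (!all(grepl("^[ACGT]+$", lib$spacer))) stop("spacers must be over A/C/G/T")
    bad <- lib$target_class == "ntc" & lib$gene != "NTC"
    if (any(bad)) stop("ntc records must have gene == 'NTC'")
  }
  invisible(lib)
}

#' Write / read a guide library as TSV
#'
#' @param lib library `data.frame`.
#' @param path file path.
#' @return `read_library` returns the library `data.frame`.
#' @export
write_library <- function(lib, path) {
  validate_library(lib)
  utils::write.table(lib, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  lib <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  validate_library(lib)
  lib
}
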