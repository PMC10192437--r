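#' @useDynLib invascreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Run `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards. Every simulation entry point routes through this so
# identical seeds give byte-identical output without clobbering the session.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

# Reverse complement for plain character vectors (DNA alphabet, N allowed).
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Canonicalize RNA/DNA input to uppercase DNA (U -> T).
as_dna_chr <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
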