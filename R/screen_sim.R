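#' Configuration for a pooled invasion-screen simulation
#'
#' Captures the study design of a genome-wide knockout invasion screen:
#' library coverage of ~500 cells per guide, transduction at MOI ~0.3 (so
#' each cell is modelled as carrying a single guide), and three rounds of
#' Matrigel invasion selection. Sequencing depth and the base invasion rate
#' are not dictated by that design and are exposed as parameters.
#'
#' @param coverage cells per sgRNA in the initial pool (default 500).
#' @param moi multiplicity of infection; values <= 1 are treated as the
#'   single-integration regime (one guide per cell). Default 0.3.
#' @param n_rounds rounds of invasion selection (default 3).
#' @param reads_per_sample sequencing reads per sample (default 1e6).
#' @param base_rate per-round invasion probability of a cell carrying a
#'   neutral (fitness 1) guide; survival probability of a cell is
#'   `base_rate * fitness / max(fitness)`. Default 0.5.
#' @param seq_error_rate per-base substitution error rate applied when reads
#'   are emitted (default 0).
#' @param frac_n_contam,frac_lowq_contam,frac_adapter_contam fractions of
#'   total emitted reads that are, respectively, N-rich, low-quality and
#'   adapter-bearing contaminants (mutually exclusive classes; default 0).
#' @param adapter adapter sequence used for adapter contaminants.
#' @param seed integer seed.
#' @return A list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(coverage = 500, moi = 0.3, n_rounds = 3,
                              reads_per_sample = 1e6, base_rate = 0.5,
                              seq_error_rate = 0,
                              frac_n_contam = 0, frac_lowq_contam = 0,
                              frac_adapter_contam = 0,
                              adapter = "AGATCGGAAGAGC", seed = 1L) {
  stopifnot(coverage >= 1, moi > 0, moi <= 1, n_rounds >= 0,
            base_rate > 0, base_rate <= 1,
            seq_error_rate >= 0, seq_error_rate < 1,
            frac_n_contam >= 0, frac_lowq_contam >= 0,
            frac_adapter_contam >= 0,
            frac_n_contam + frac_lowq_contam + frac_adapter_contam <= 1)
  structure(list(coverage = coverage, moi = moi, n_rounds = n_rounds,
                 reads_per_sample = reads_per_sample, base_rate = base_rate,
                 seq_error_rate = seq_error_rate,
                 frac_n_contam = frac_n_contam,
                 frac_lowq_contam = frac_lowq_contam,
                 frac_adapter_contam = frac_adapter_contam,
                 adapter = adapter, seed = as.integer(seed)),
            class = "screen_sim_config")
}

#' Simulate a pooled knockout invasion screen
#'
#' Generative model: a cell pool of `coverage * n_guides` cells is seeded
#' multinomially over the guides (uniform representation). In each selection
#' round every cell survives independently with probability
#' `base_rate * fitness(gene) / max(fitness)` and the pool is resampled back
#' to constant size, so the expected selected/input abundance ratio of a
#' guide is proportional to `fitness^n_rounds`. Read counts for the input
#' (pre-selection) and selected (post-selection) samples are multinomial
#' draws of `reads_per_sample` reads from the respective pool proportions.
#'
#' @param library guide library from [make_library()].
#' @param truth named numeric vector mapping gene -> invasion fitness
#'   (1 = neutral, < 1 = knockout impairs invasion, i.e. the gene is a
#'   driver). Genes absent from `truth` default to 1; NTC guides are always
#'   neutral.
#' @param config [screen_sim_config()].
#' @return A list with `input_counts` and `selected_counts` (a two-sample
#'   [count_table()] is in `counts`), and `truth_log`, a data.frame of the
#'   per-gene fitness actually used plus a `driver` flag (fitness < 1).
#' @export
simulate_screen <- function(library, truth = numeric(0),
                            config = screen_sim_config()) {
  validate_library(library)
  if (nrow(library) == 0) stop("empty library")
  if (config$reads_per_sample <= 0) stop("reads_per_sample must be positive")
  fit <- resolve_fitness(library, truth)
  if (any(fit < 0)) stop("fitness values must be nonnegative")
  n <- nrow(library)
  pool_size <- round(config$coverage * n)

  res <- with_seed(config$seed, {
    pool <- as.vector(stats::rmultinom(1, pool_size, rep(1 / n, n)))
    input_pool <- pool
    surv_p <- config$base_rate * fit / max(fit)
    for (r in seq_len(config$n_rounds)) {
      survivors <- stats::rbinom(n, pool, surv_p)
      if (sum(survivors) == 0) stop("entire pool lost during selection")
      pool <- as.vector(stats::rmultinom(1, pool_size, survivors / sum(survivors)))
    }
    input_reads <- as.vector(
      stats::rmultinom(1, config$reads_per_sample, input_pool / sum(input_pool)))
    selected_reads <- as.vector(
      stats::rmultinom(1, config$reads_per_sample, pool / sum(pool)))
    list(input = input_reads, selected = selected_reads)
  })

  m <- cbind(Input = res$input, Selected = res$selected)
  rownames(m) <- library$sgrna_id
  tab <- count_table(m, stats::setNames(library$gene, library$sgrna_id))
  genes <- unique(library$gene)
  truth_log <- data.frame(
    gene = genes,
    fitness = fit[match(genes, library$gene)],
    driver = fit[match(genes, library$gene)] < 1,
    stringsAsFactors = FALSE
  )
  list(counts = tab,
       input_counts = tab$counts[, "Input"],
       selected_counts = tab$counts[, "Selected"],
       truth_log = truth_log)
}

resolve_fitness <- function(library, truth) {
  fit <- rep(1, nrow(library))
  if (length(truth)) {
    if (is.null(names(truth))) stop("truth must be a named gene -> fitness vector")
    hit <- match(library$gene, names(truth))
    fit[!is.na(hit)] <- truth[hit[!is.na(hit)]]
  }
  fit[library$target_class == "ntc"] <- 1
  unname(fit)
}
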