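Package: invascreen
Title: Pooled CRISPR Invasion Screen Analysis with Expression, Methylation
    and Clinical Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for pooled CRISPR knockout invasion screens:
    FASTQ quality filtering, sgRNA read assignment, transcripts-per-million
    normalization, fold-change and empirical-null depletion calling,
    Kolmogorov-Smirnov gene aggregation and library-diversity summaries;
    integration of screen hits with differential-expression tables and
    miRNA seed-site scans; promoter CpG-island prediction and bisulfite
    methylation summaries; tissue-microarray contingency statistics,
    rank correlation and Kaplan-Meier/log-rank survival comparison. A
    synthetic-data module simulates every input (screen counts, reads with
    contaminants, bisulfite pileups, expression tables, 3'UTRs with planted
    seed sites, clinical cohorts) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    survival,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
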