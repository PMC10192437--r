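---
title: "Methods: pooled CRISPR invasion-screen analysis and its companions"
author: "invascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled CRISPR invasion-screen analysis and its companions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invascreen)
```

# The problem

A pooled CRISPR knockout invasion screen transduces a cancer cell line with
a genome-scale guide library (GeCKOv2-like: ~6 sgRNAs per protein-coding
gene, 4 per miRNA, at a multiplicity of infection low enough that each cell
carries one guide and ~500 cells represent each guide) and passes the pool
through repeated rounds of Matrigel invasion selection. Guides that knock
out genes required for invasion fall in abundance between the pre-selection
(input) and post-selection (selected) samples. This package implements the
downstream computation: read QC and guide quantification, normalization,
depletion calling, gene aggregation, intersection with expression profiling,
and the ancillary analyses that such a study runs around the screen (miRNA
seed-site scanning, promoter CpG/methylation summaries, tissue-microarray
association statistics, and Kaplan–Meier survival comparison).

# The depletion model

## Normalization and fold change

Counts are normalized within each sample to transcripts per million,
`TPM = count / total clean-tag count * 1e6`, so each sample column sums to
one million and normalization is invariant to sequencing depth. The
per-guide effect size is the ratio
`fc = (TPM_selected + c) / (TPM_input + c)` with a pseudocount `c` of 1 TPM
on both sides. The pseudocount is a package choice: it avoids division by
zero for guides that drop out entirely and shrinks the most extreme ratios;
at 1 TPM it is negligible for any guide near the library mean (~154 TPM in
a 6,500-guide library).

## Significance

The screen design has a single sequenced sample per arm, so no per-guide
two-sample test can be formed from replicates. The per-guide p-value is an
empirical tail probability against a null distribution of log2 fold
changes: `p = (#null <= log2fc + 1) / (n_null + 1)`, using the
non-targeting controls (NTCs) as the null when the library contains them,
otherwise all guides. A guide belonging to the null set is scored
leave-one-out. The add-one form keeps p in (0, 1] and makes the p-values
super-uniform under the null (verified as a property test). With `n` NTCs
the smallest attainable p is `1/(n+1)`; a library needs at least ~200 NTCs
before the default threshold of 0.005 can ever be crossed, which is why the
p-value routine warns below 50 null guides.

A guide is called significantly depleted when `fc < 0.5` and `p < 0.005`,
both strictly — the boundary semantics follow the stated thresholds
literally, and `call_depleted()` is tested at the boundary values.

## Gene level

Genes are aggregated by counting depleted guides (`min_depleted` defaults
to 1, exposed because the appropriate stringency depends on the library's
guides-per-gene) and by a two-sample Kolmogorov–Smirnov test of the gene's
guide log2 fold changes against all other guides. The KS p-value is exact
when the combined sample size is at most 10 and asymptotic otherwise; the
exact branch is verified against an exhaustive enumeration oracle. Gene
rows are sorted by depleted-guide count, then KS p, then mean log2 fold
change.

Library diversity is summarized by the cumulative sgRNA frequency curve
(a Lorenz curve over guides sorted by ascending count), its Gini
coefficient, and the fraction of dropout (zero-count) guides. Invasion
selection concentrates reads in surviving clones, so the selected sample's
Gini exceeds the input's.

# Read processing

Raw reads pass three stringent filters, applied in order with first-rule
attribution: (1) at least 10% unidentified nucleotides (N), boundary
inclusive; (2) more than 40% of bases at Phred quality <= 20, boundary
exclusive; (3) an exact substring match to the barcode adapter or its
reverse complement. The mixed boundary semantics follow the stated rules
verbatim. The adapter sequence and both thresholds are configurable because
the actual barcode adapter of any given protocol varies.

Clean reads are assigned by scanning every library spacer against every
read offset with a Hamming tolerance of `max_mismatch` (default 1, range
0–2); `N` never matches. The default of one mismatch mirrors a
word-size-18 alignment regime on 20-nt spacers: a single edge mismatch
still leaves an exact 18-mer. Full local alignment is deliberately not
reimplemented. A read counts toward a guide only when exactly one distinct
guide matches; reads matching none are tallied unassigned, reads matching
several are ambiguous and discarded rather than fractionally assigned (the
conservative choice). Assigned + unassigned + ambiguous equals the clean
read count per sample, an invariant the tests assert.

# The synthetic screen

The generator's defaults are the study conditions: coverage 500 cells per
guide, MOI 0.3 treated as the single-integration regime, three rounds of
selection. Selection is modelled per round as independent Bernoulli
survival with probability `base_rate * fitness(gene) / max(fitness)`
followed by multinomial resampling of the pool back to constant size; the
expected selected/input abundance ratio of a guide is then proportional to
`fitness^n_rounds`, which the tests check against the closed form. The
base invasion rate (default 0.5/round) and sequencing depth are not implied
by the design and are exposed as configuration. Read counts are multinomial
draws per sample; FASTQ emission embeds each spacer at a fixed offset
inside constant vector context (the real amplicon structure is not
modelled) and appends mutually exclusive contaminant classes engineered to
fail exactly one QC rule each.

What the simulator does not emulate: PCR duplicates and amplification bias,
GC bias, paired-end reads, guide-specific cutting efficiency, multi-guide
integration at higher MOI, and clonal drift unrelated to invasion. Passing
recovery tests therefore demonstrates that the pipeline's accounting and
thresholds behave as specified under the stated generative model — not that
the thresholds are optimal for any particular real screen.

Problem sizes used in the tests and in `scripts/acceptance.R` are scaled to
a 6,500-guide library (1,000 genes + 500 NTCs) at 2e6 reads per sample with
50 planted drivers at fitness 0.2 — large enough that recall and false-call
rates are stable, small enough to run in seconds. Every simulation entry point takes
an explicit integer seed and restores the caller's RNG state, so identical
seeds give byte-identical outputs.

# Integration screens

Up-regulated genes are those with fold change strictly above 2.0 and
BH-adjusted q strictly below 0.001 (BH applied internally when only raw p
is supplied). The candidate shortlist is the intersection with the screen's
gene list, ranked by depleted-guide count, then gene KS p, then expression
fold change, with lexicographic tie-breaks — the published shortlist of
such studies is ranked but the criterion unstated, so this ordering is a
documented package convention and reorderable by the caller.

The miRNA site scanner reports TargetScan-style canonical classes anchored
at each match to the reverse complement of seed positions 2–7: `8mer`
(positions 2–8 matched plus `A` opposite position 1), `7mer-m8` (2–8
alone), `7mer-A1` (2–7 plus the `A`). One site per register, overlapping
registers all reported, no G:U wobble, U/T equivalent on input. A single
seed-match engine replaces multi-program consensus voting, which is out of
scope. Since the published class used for "perfect" seed matching is not
recoverable, all three classes are reported and filterable downstream.

# Methylation

CpG islands are predicted with a Gardiner-Garden-style sliding window using
MethPrimer-like defaults (window 200, GC >= 0.5, observed/expected CpG
>= 0.6 with `obs/exp = n_CpG * L / (n_C * n_G)`, minimum length 200), all
four tunable since the original web tool's exact parameterization is not
recoverable. Overlapping passing windows are merged; a merged region
failing the whole-region test is trimmed to the longest sub-interval
spanned by consecutive passing windows that passes (leftmost on ties) — a
deterministic rule verified against a brute-force enumeration oracle.
`N` counts as non-C/non-G.

Per-CpG methylation fractions use the inclusive depth >= 4 rule; sites
below depth are flagged excluded, never imputed. Region summaries report
CpG density (CG dinucleotides per bp) and GC content on the forward strand,
and a mean fraction over passing sites that is NA — not 0 — when no site
passes. Two regions are compared by mean difference with delta = 0.25, a
package convention for "heavily" hyper/hypomethylated; the threshold is a
parameter.

# Clinical statistics

Staining scores 0–3 dichotomize as 0–1 low vs 2–3 high. The paired
up-regulation fraction counts tumor/normal ratios strictly above 1.
Contingency tables are tested with the uncorrected Pearson chi-square
(closed form `N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))`) or the Yates-corrected
variant with each cell term clamped at zero, because published
tissue-microarray tables mix conventions: some rows reproduce only
uncorrected, and a balanced age row reproduces exactly (p = 1.000) only
with the clamped correction. Both variants are therefore exposed and the
analysis reports both where it matters, alongside the Fisher exact test
(two-sided by the point-probability rule) for sparse cells. Rank
correlation is Spearman with exact permutation p for n <= 8 and the t
approximation above. Survival uses the Kaplan–Meier product-limit estimate
(median = first time the estimate drops to <= 0.5) and the standard
two-group log-rank test via the survival package; group labels are taken
as given, with no data-driven cutpoint search.

# Numerical and degenerate-input choices

* All-zero count columns, zero-margin 2x2 tables, constant vectors in
  correlation, groups without events, and undefined methylation means fail
  loudly with informative errors instead of returning sentinel numbers.
* Empirical p-values are never 0; chi-square p-values come from the df-1
  upper tail (`pchisq(..., lower.tail = FALSE)`).
* Fisher's point-probability comparison uses the conventional relative
  tolerance (1 + 1e-7) so ties at machine precision count as "as extreme".
* The spacer matcher treats `N` as matching nothing, so N-rich reads can
  never be assigned even if they survive QC with permissive rules.

# Known limitations

* The per-guide empirical-null p-value is a pragmatic replacement for an
  under-specified per-guide test; it is exchangeable-rank-based and
  discrete, so its resolution is limited by the NTC count.
* No replicate-aware variance modelling (single sample per arm by design)
  and no MAGeCK-style rank aggregation; the gene list is threshold-based.
* Seed-site scanning is sequence-only: no context scoring, conservation,
  or duplex thermodynamics.
* The methylation module starts from pileups; bisulfite read alignment is
  upstream and out of scope.

# Worked example

```{r example}
lib <- make_library(100, 6, 0, 0, 200, seed = 1)
drivers <- unique(lib$gene)[1:5]
sim <- simulate_screen(lib, setNames(rep(0.2, 5), drivers),
                       screen_sim_config(reads_per_sample = 5e5, seed = 1))
tpm <- tpm_normalize(sim$counts)
rec <- sgrna_fold_changes(tpm, "Input", "Selected", sim$counts)
rec <- sgrna_depletion_pvalues(rec, "ntc")
rec <- call_depleted(rec)
aggregate_genes(rec)
```
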