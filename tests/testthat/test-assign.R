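fixed_lib <- function() {
  data.frame(
    sgrna_id = c("sg_001", "sg_002", "sg_003"),
    gene = c("A", "A", "B"),
    target_class = "protein_coding",
    spacer = c("ACGTACGTACGTACGTACGT",
               "TTTTCCCCGGGGAAAATTTT",
               "GATCGATCGATCGATCGAAA"),
    stringsAsFactors = FALSE
  )
}

embed <- function(spacer, pre = "AAAAA", post = "CCCCC") {
  paste0(pre, spacer, post)
}

as_reads <- function(bases) {
  fastq_reads(paste0("r", seq_along(bases)), bases,
              vapply(nchar(bases), function(w) strrep("I", w), ""))
}

test_that("exact embeds are counted once and junk reads are unassigned", {
  lib <- fixed_lib()
  reads <- as_reads(c(embed(lib$spacer[1]), strrep("A", 30)))
  tab <- assign_sgrnas(reads, lib, max_mismatch = 0, sample = "S")
  expect_equal(unname(tab$counts["sg_001", "S"]), 1L)
  expect_equal(sum(tab$counts), 1L)
  expect_equal(unname(tab$unassigned), 1)
  expect_equal(unname(tab$ambiguous), 0)
})

test_that("reads matching two distinct guides are ambiguous, not counted", {
  lib <- fixed_lib()
  double <- paste0("AA", lib$spacer[1], "TT", lib$spacer[3], "GG")
  tab <- assign_sgrnas(as_reads(double), lib, max_mismatch = 0, sample = "S")
  expect_equal(sum(tab$counts), 0L)
  expect_equal(unname(tab$ambiguous), 1)
  # same guide at two offsets is NOT ambiguous
  twice <- paste0(lib$spacer[2], "A", lib$spacer[2])
  tab <- assign_sgrnas(as_reads(twice), lib, max_mismatch = 0, sample = "S")
  expect_equal(unname(tab$counts["sg_002", "S"]), 1L)
})

test_that("mismatch tolerance follows max_mismatch including edge mutations", {
  lib <- fixed_lib()
  sp <- lib$spacer[1]
  mut1 <- sp
  substr(mut1, 1, 1) <- "G"        # edge mutation: exact 18-mer retained
  expect_true(grepl(substr(sp, 3, 20), mut1, fixed = TRUE))
  mut_mid <- sp
  substr(mut_mid, 10, 10) <- "A"  # mid-spacer mutation (position 10 is C)
  for (read in list(embed(mut1), embed(mut_mid))) {
    t0 <- assign_sgrnas(as_reads(read), lib, max_mismatch = 0, sample = "S")
    t1 <- assign_sgrnas(as_reads(read), lib, max_mismatch = 1, sample = "S")
    expect_equal(sum(t0$counts), 0L)
    expect_equal(unname(t1$counts["sg_001", "S"]), 1L)
  }
  mut2 <- sp
  substr(mut2, 1, 1) <- "G"; substr(mut2, 20, 20) <- "C"
  t1 <- assign_sgrnas(as_reads(embed(mut2)), lib, max_mismatch = 1, sample = "S")
  t2 <- assign_sgrnas(as_reads(embed(mut2)), lib, max_mismatch = 2, sample = "S")
  expect_equal(sum(t1$counts), 0L)
  expect_equal(unname(t2$counts["sg_001", "S"]), 1L)
})

test_that("N bases never match and revcomp flag enables reverse-strand hits", {
  lib <- fixed_lib()
  withN <- embed(paste0("N", substr(lib$spacer[1], 2, 20)))
  t0 <- assign_sgrnas(as_reads(withN), lib, max_mismatch = 0, sample = "S")
  t1 <- assign_sgrnas(as_reads(withN), lib, max_mismatch = 1, sample = "S")
  expect_equal(sum(t0$counts), 0L)
  expect_equal(unname(t1$counts["sg_001", "S"]), 1L)

  rc_read <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(embed(lib$spacer[3]))))
  fwd <- assign_sgrnas(as_reads(rc_read), lib, sample = "S")
  both <- assign_sgrnas(as_reads(rc_read), lib, sample = "S", revcomp = TRUE)
  expect_equal(sum(fwd$counts), 0L)
  expect_equal(unname(both$counts["sg_003", "S"]), 1L)
})

test_that("assignment partitions clean reads per sample", {
  set.seed(42)
  lib <- make_library(30, 4, 0, 0, 10, seed = 12)
  m <- matrix(rpois(nrow(lib), 20), ncol = 1,
              dimnames = list(lib$sgrna_id, "S1"))
  tab <- count_table(m, stats::setNames(lib$gene, lib$sgrna_id))
  dir <- withr::local_tempdir()
  cfg <- screen_sim_config(frac_n_contam = 0.05, frac_lowq_contam = 0.05,
                           frac_adapter_contam = 0.05, seed = 77)
  q <- quantify_fastq(emit_fastq(tab, lib, cfg, dir), lib)
  expect_equal(sum(q$counts$counts) + unname(q$counts$unassigned) +
                 unname(q$counts$ambiguous),
               q$qc$kept)
  # error-free clean reads are all recovered at their encoded guides
  expect_equal(q$counts$counts[, "S1"], m[, "S1"])
})

test_that("library problems are rejected", {
  lib <- fixed_lib()
  dup <- rbind(lib, lib[1, ])
  dup$sgrna_id[4] <- "sg_004"
  expect_error(assign_sgrnas(as_reads("ACGT"), dup), "duplicate spacers")
  expect_error(assign_sgrnas(as_reads("ACGT"), lib, max_mismatch = 3),
               "max_mismatch")
})
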