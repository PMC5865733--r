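test_that("simulation is byte-identical under a fixed seed", {
  cfg <- tiny_config(seed = 7)
  s1 <- build_transcriptome(cfg)
  s2 <- build_transcriptome(cfg)
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(s1$models, s2$models)
  expect_identical(s1$truth, s2$truth)
  l1 <- simulate_library(s1, "FP", "C25", 1)
  l2 <- simulate_library(s2, "FP", "C25", 1)
  expect_identical(l1, l2)
  # a different replicate uses a different stream
  l3 <- simulate_library(s1, "FP", "C25", 2)
  expect_false(identical(l1$sequence, l3$sequence))
})

test_that("configuration validation rejects degenerate inputs", {
  expect_error(simulation_config(cds_len_range = c(500, 300)), "degenerate")
  expect_error(simulation_config(utr_leakage = 1.5), "utr_leakage")
  expect_error(simulation_config(rrna_fraction = 2), "rrna_fraction")
  bad_fp <- c(0.5, 0.3, 0.2, rep(0, 6))   # mode at 26 nt, not 31-33
  expect_error(simulation_config(fp_length_dist = bad_fp), "31-33")
  bad_sum <- rep(0.2, 9)
  expect_error(simulation_config(ct_length_dist = bad_sum), "sum to 1")
})

test_that("organelle copies are planted at the requested identity", {
  cfg <- tiny_config(seed = 11)
  sim <- build_transcriptome(cfg)
  m <- sim$models
  cp <- sim$organelles$chloroplast
  # identity 1.0: nuclear CDS identical to the chloroplast gene
  i1 <- which(m$organelle_source == "chloroplast_gene_01")
  cds1 <- substr(sim$sequences[m$transcript_id[i1]],
                 m$cds_start[i1] + 1, m$cds_end[i1])
  expect_identical(unname(cds1), unname(cp$cds_seq[["chloroplast_gene_01"]]))
  # identity 0.85: mismatch count equals round(0.15 * length)
  i2 <- which(m$organelle_source == "chloroplast_gene_02")
  cds2 <- substr(sim$sequences[m$transcript_id[i2]],
                 m$cds_start[i2] + 1, m$cds_end[i2])
  ref <- cp$cds_seq[["chloroplast_gene_02"]]
  diffs <- sum(strsplit(cds2, "")[[1]] != strsplit(ref, "")[[1]])
  expect_equal(diffs, round(0.15 * nchar(ref)))
})

test_that("emitted GFF3 and FASTA agree on region partitions (re-parse oracle)", {
  cfg <- tiny_config(seed = 3)
  sim <- build_transcriptome(cfg)
  dir <- withr::local_tempdir()
  libs <- list(C25CT_rep1 = simulate_library(sim, "CT", "C25", 1))
  write_fixture(sim, dir, libraries = libs)
  models2 <- read_models_gff3(file.path(dir, "annotation.gff3"))
  seqs2 <- Biostrings::readDNAStringSet(file.path(dir, "transcriptome.fasta"))
  m2 <- models2[match(sim$models$transcript_id, models2$transcript_id), ]
  # utr5 + cds + utr3 lengths sum to the FASTA sequence length
  utr5 <- m2$cds_start
  cds <- m2$cds_end - m2$cds_start
  utr3 <- m2$length - m2$cds_end
  expect_true(all(utr5 >= 0 & cds > 0 & utr3 >= 0))
  expect_equal(utr5 + cds + utr3,
               unname(Biostrings::width(seqs2)[match(m2$transcript_id, names(seqs2))]))
  expect_equal(m2$cds_start, sim$models$cds_start)
  expect_equal(m2$cds_end, sim$models$cds_end)
  expect_equal(m2$is_rdna, sim$models$is_rdna)
})

test_that("library composition follows the configured mixture", {
  cfg <- tiny_config(seed = 19)
  sim <- build_transcriptome(cfg)
  fp <- simulate_library(sim, "FP", "C100", 1)
  expect_equal(nrow(fp), cfg$reads_per_library)
  # rDNA share within 3 binomial standard errors of rrna_fraction
  rdna_share <- mean(startsWith(fp$source_id, "rDNA."))
  se <- sqrt(cfg$rrna_fraction * (1 - cfg$rrna_fraction) / cfg$reads_per_library)
  expect_lt(abs(rdna_share - cfg$rrna_fraction), 3 * se)
  # modal FP length in 31-33, modal CT length in 26-28
  expect_true(as.integer(names(which.max(table(fp$length)))) %in% 31:33)
  ct <- simulate_library(sim, "CT", "C100", 1)
  expect_true(as.integer(names(which.max(table(ct$length)))) %in% 26:28)
  # reads are exact substrings of their source transcripts
  idx <- sample.int(nrow(fp), 200)
  expect_identical(
    unname(substr(sim$sequences[fp$source_id[idx]], fp$start[idx] + 1,
                  fp$start[idx] + fp$length[idx])),
    fp$sequence[idx])
})

test_that("zero UTR leakage confines all footprint reads to the CDS", {
  cfg <- tiny_config(seed = 23, utr_leakage = 0)
  sim <- build_transcriptome(cfg)
  fp <- simulate_library(sim, "FP", "C25", 1)
  fp <- fp[!startsWith(fp$source_id, "rDNA."), ]
  mi <- match(fp$source_id, sim$models$transcript_id)
  expect_true(all(fp$start >= sim$models$cds_start[mi]))
  expect_true(all(fp$start + fp$length <= sim$models$cds_end[mi]))
})

test_that("FP/CT read-density ratio recovers true TE for well-covered genes", {
  cfg <- tiny_config(seed = 29, reads_per_library = 40000)
  sim <- build_transcriptome(cfg)
  ct <- simulate_library(sim, "CT", "C100", 1)
  fp <- simulate_library(sim, "FP", "C100", 1)
  tr <- sim$truth[sim$truth$stage == "C100", ]
  L <- sim$models$length[match(tr$transcript_id, sim$models$transcript_id)]
  w <- tr$ct_abundance * L
  expected <- w / sum(w) * sum(!startsWith(ct$source_id, "rDNA."))
  ct_n <- table(factor(ct$source_id, levels = tr$transcript_id))
  fp_n <- table(factor(fp$source_id, levels = tr$transcript_id))
  sel <- expected >= 200 & tr$te_true > 0.2    # FP depth >= ~40 reads
  ratio <- (as.numeric(fp_n) / sum(fp_n)) / (as.numeric(ct_n) / sum(ct_n))
  expect_true(all(abs(ratio[sel] / tr$te_true[sel] - 1) < 0.2))
})

test_that("fixture writing round-trips and is checksum-stable", {
  cfg <- tiny_config(seed = 31, reads_per_library = 500)
  sim <- build_transcriptome(cfg)
  libs <- simulate_all_libraries(sim)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_fixture(sim, d1, libraries = libs)
  m2 <- write_fixture(sim, d2, libraries = libs)
  expect_identical(m1$md5, m2$md5)
  # FASTQ round-trip: record count and sequences preserved
  rd <- read_reads_fastq(file.path(d1, "C25FP_rep1.fastq"))
  expect_equal(nrow(rd), 500)
  expect_identical(rd$sequence, libs$C25FP_rep1$sequence)
  expect_identical(rd$read_id, libs$C25FP_rep1$read_id)
  # truth table round-trip
  tr <- read.delim(file.path(d1, "truth.tsv"), stringsAsFactors = FALSE)
  expect_equal(nrow(tr), nrow(sim$truth))
  expect_equal(tr$te_true, sim$truth$te_true, tolerance = 1e-12)
})
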