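test_that("index locates exact occurrences at the right offsets", {
  idx <- build_index(c(tx1 = "ACGTACGT"), k = 4)
  al <- align_reads(data.frame(read_id = "r1", sequence = "GTAC"), idx)
  expect_equal(al$hits$start, 2L)
  expect_equal(al$hits$transcript_id, "tx1")
  # empty transcript set: any query yields no hits
  empty <- build_index(character(0), k = 4)
  al2 <- align_reads(data.frame(read_id = "r1", sequence = "GTAC"), empty)
  expect_equal(nrow(al2$hits), 0L)
  expect_equal(al2$summary[["n_unaligned"]], 1L)
  expect_error(build_index(c(a = "ACGTACGT", a = "ACGTACGT")), "duplicate")
})

test_that("overlapping occurrences within one transcript are all reported", {
  idx <- build_index(c(tx = strrep("A", 30)), k = 4)
  al <- align_reads(data.frame(read_id = "r", sequence = strrep("A", 25)),
                    idx, max_multimap = 25)
  expect_equal(nrow(al$hits), 6L)          # starts 0..5
  expect_equal(sort(al$hits$start), 0:5)
})

test_that("aligner output set-equals brute-force search on random instances", {
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  for (rep_i in 1:3) {
    n_tx <- 60
    seqs <- vapply(sample(80:400, n_tx, TRUE),
                   function(L) paste(sample(bases, L, TRUE), collapse = ""), "")
    names(seqs) <- sprintf("tx%03d", seq_len(n_tx))
    # paralog: duplicate one transcript so multimapping occurs
    seqs[n_tx] <- seqs[1]
    # queries: true substrings, mismatched copies, and random sequences
    reads <- list()
    for (i in 1:120) {
      src <- sample.int(n_tx, 1)
      rl <- sample(26:34, 1)
      p <- sample.int(nchar(seqs[src]) - rl, 1)
      s <- substr(seqs[src], p, p + rl - 1)
      if (i %% 3 == 0) substr(s, sample.int(rl, 1), rl) <- "N"  # guaranteed mismatch
      reads[[i]] <- s
    }
    reads <- c(unlist(reads),
               vapply(1:30, function(i) paste(sample(bases, 30, TRUE), collapse = ""), ""))
    rdf <- data.frame(read_id = sprintf("q%04d", seq_along(reads)),
                      sequence = reads, stringsAsFactors = FALSE)
    idx <- build_index(seqs)
    got <- sort_hits(align_reads(rdf, idx)$hits)
    want <- sort_hits(brute_force_hits(rdf, as.list(seqs)))
    expect_identical(got, want)
  }
})

test_that("reads above the multimap cap are suppressed entirely", {
  common <- paste(sample(c("A","C","G","T"), 30, TRUE), collapse = "")
  mk <- function(i) paste0(paste(sample(c("A","C","G","T"), 40, TRUE), collapse = ""),
                           common)
  set.seed(1)
  seqs <- stats::setNames(vapply(1:26, mk, ""), sprintf("tx%02d", 1:26))
  idx <- build_index(seqs)
  rdf <- data.frame(read_id = "r", sequence = common)
  al25 <- align_reads(rdf, idx, max_multimap = 25)
  expect_equal(nrow(al25$hits), 0L)
  expect_equal(al25$summary[["n_suppressed"]], 1L)
  al26 <- align_reads(rdf, idx, max_multimap = 26)
  expect_equal(nrow(al26$hits), 26L)
})

test_that("raising the multimap cap never decreases emitted hits", {
  cfg <- tiny_config(seed = 13, reads_per_library = 2000)
  sim <- build_transcriptome(cfg)
  idx <- build_index(sim$sequences)
  lib <- simulate_library(sim, "CT", "C25", 1)
  n_prev <- -1L
  for (cap in c(1L, 2L, 25L)) {
    n <- nrow(align_reads(lib, idx, max_multimap = cap)$hits)
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("error-free reads all align; mismatched reads do not", {
  cfg <- tiny_config(seed = 17, reads_per_library = 3000)
  sim <- build_transcriptome(cfg)
  idx <- build_index(sim$sequences)
  lib <- simulate_library(sim, "CT", "C300", 2)
  al <- align_reads(lib, idx)
  expect_equal(al$summary[["n_unaligned"]], 0L)
  expect_equal(al$summary[["n_aligned_reads"]] + al$summary[["n_suppressed"]],
               nrow(lib))
  # every non-suppressed read aligns at least to its source transcript
  src_hit <- paste(al$hits$read_id, al$hits$transcript_id)
  not_suppressed <- lib$read_id %in% al$hits$read_id
  expect_true(all(paste(lib$read_id, lib$source_id)[not_suppressed] %in% src_hit))
  # with sequencing errors, mutated reads fail the zero-mismatch contract
  cfg_e <- tiny_config(seed = 17, reads_per_library = 3000, error_rate = 0.02)
  sim_e <- build_transcriptome(cfg_e)
  lib_e <- simulate_library(sim_e, "CT", "C300", 2)
  al_e <- align_reads(lib_e, build_index(sim_e$sequences))
  expect_gt(al_e$summary[["n_unaligned"]], 0L)
  expect_error(align_reads(lib, idx, mismatches_allowed = 1), "reserved")
})

test_that("rDNA exclusion removes the flagged models and their hits", {
  # the reference-set bookkeeping: 88,647 models minus 132 rDNA = 88,515
  models <- data.frame(transcript_id = sprintf("m%06d", 1:88647),
                       is_rdna = c(rep(TRUE, 132), rep(FALSE, 88515)))
  ex <- exclude_rdna(models, data.frame(read_id = character(0),
                                        transcript_id = character(0)))
  expect_equal(ex$removed_models, 132L)
  expect_equal(nrow(ex$models), 88515L)

  cfg <- tiny_config(seed = 5, rrna_fraction = 0.5, reads_per_library = 4000)
  sim <- build_transcriptome(cfg)
  idx <- build_index(sim$sequences)
  lib <- simulate_library(sim, "CT", "C25", 1)
  al <- align_reads(lib, idx)
  ex2 <- exclude_rdna(sim$models, al$hits)
  # removed share matches the truth composition of the library
  n_rdna_reads <- sum(startsWith(lib$source_id, "rDNA."))
  expect_equal(ex2$removed_hits, n_rdna_reads)   # rDNA models are unique seqs
  expect_false(any(ex2$hits$transcript_id %in%
                     sim$models$transcript_id[sim$models$is_rdna]))
  # zero rDNA flags: identity on hits
  no_r <- sim$models; no_r$is_rdna <- FALSE
  expect_identical(exclude_rdna(no_r, al$hits)$hits, al$hits)
})

test_that("hit counting follows the one-count-per-alignment rule", {
  models <- data.frame(transcript_id = c("A.1", "B.1"), is_rdna = FALSE)
  h <- data.frame(read_id = c("r1", "r1"), transcript_id = c("A.1", "B.1"),
                  start = 0L, length = 30L)
  cm <- count_hits(list(C25CT_rep1 = h), models)
  expect_equal(unname(cm$counts[, 1]), c(1L, 1L))
  expect_equal(unname(cm$total_mapped), 2L)
  # no hits: all-zero matrix
  cm0 <- count_hits(list(C25CT_rep1 = h[0, ]), models)
  expect_true(all(cm0$counts == 0L))
  expect_equal(unname(cm0$total_mapped), 0L)
  # unknown transcript is an error
  h_bad <- data.frame(read_id = "r", transcript_id = "C.1", start = 0L, length = 30L)
  expect_error(count_hits(list(C25CT_rep1 = h_bad), models), "unknown transcript")
  # column sums equal an independent tally of emitted hits
  cfg <- tiny_config(seed = 37, reads_per_library = 2000)
  sim <- build_transcriptome(cfg)
  al <- align_reads(simulate_library(sim, "FP", "C25", 1),
                    build_index(sim$sequences))
  ex <- exclude_rdna(sim$models, al$hits)
  cm2 <- count_hits(list(C25FP_rep1 = ex$hits), ex$models)
  expect_equal(unname(cm2$total_mapped), nrow(ex$hits))
  tally <- table(factor(ex$hits$transcript_id, levels = ex$models$transcript_id))
  expect_equal(unname(cm2$counts[, 1]), as.integer(tally))
})
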