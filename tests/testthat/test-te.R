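test_that("TE worked examples reproduce the published ratios exactly", {
  ex <- extdata("te_worked_examples.tsv")
  te <- compute_te(ex$ct_rpkm, ex$fp_rpkm)
  expect_equal(te$te_round, ex$ref_te)
  # floored degenerate pair gives TE exactly 1
  expect_equal(compute_te(0.1, 0.1)$te_round, 1.00)
})

test_that("zero hit counts are converted to one for the test only", {
  m <- matrix(c(0L, 5L, 0L, 0L), 1, 4,
              dimnames = list("g.1", c("C25CT_rep1", "C25CT_rep2",
                                       "C25FP_rep1", "C25FP_rep2")))
  cm <- structure(list(counts = m,
                       libraries = riboTE:::.parse_library_key(colnames(m)),
                       total_mapped = colSums(m)), class = "count_matrix")
  tc <- prepare_test_counts(cm, "C25")
  expect_equal(unname(tc$counts[1, ]), c(1L, 5L, 1L, 1L))
  # all-positive rows unchanged; altered cells equal zero cells
  set.seed(4)
  big <- matrix(rpois(400, 2), 100, 4)
  out <- prepare_test_counts(big)
  expect_equal(sum(out != big), sum(big == 0))
  expect_identical(out[big > 0], big[big > 0])
  expect_error(prepare_test_counts(cm, "C999"), "not present")
})

test_that("size factors follow the median-of-ratios definition", {
  set.seed(5)
  # odd transcript count: the median is a single order statistic, so the
  # ratio-scale and log-scale medians coincide exactly
  k <- matrix(rnbinom(804, mu = 50, size = 5) + 1L, 201, 4)
  expect_equal(size_factors(cbind(k[, 1], k[, 1])), c(1, 1))
  sf2 <- size_factors(cbind(k[, 1], k[, 1] * 2L))
  expect_equal(sf2[2] / sf2[1], 2)
  # literal formula evaluation as the oracle
  sf <- size_factors(k)
  gm <- exp(rowMeans(log(k)))
  for (j in 1:4) expect_equal(sf[j], median(k[, j] / gm))
  expect_error(size_factors(matrix(0L, 3, 2)), "all-positive")
})

test_that("the NB exact test is symmetric under the null and powerful when extreme", {
  p_null <- nb_test(matrix(c(10L, 10L), 1), matrix(c(10L, 10L), 1),
                    sf = rep(1, 4), dispersions = 0.01)
  expect_gte(p_null, 0.99)
  p_ext <- nb_test(matrix(c(1000L, 1000L), 1), matrix(c(10L, 10L), 1),
                   sf = rep(1, 4), dispersions = 0.01)
  expect_lt(p_ext, 1e-6)
  expect_error(nb_test(matrix(1.5, 1), matrix(2L, 1)), "integers")
})

test_that("NB test agrees with direct tail summation on a small case", {
  ct <- matrix(c(30L, 34L), 1); fp <- matrix(c(6L, 8L), 1)
  disp <- 0.05
  p <- nb_test(ct, fp, sf = rep(1, 4), dispersions = disp)
  # independent oracle: literal summation over all splits of the total
  kA <- sum(ct); kB <- sum(fp); kS <- kA + kB
  q <- (kA + kB) / 4
  mu <- q * 2
  v <- mu + disp * q^2 * 2
  sz <- mu^2 / (v - mu)
  pr <- dnbinom(0:kS, size = sz, mu = mu) *
    dnbinom(kS - (0:kS), size = sz, mu = mu)
  p_oracle <- sum(pr[pr <= pr[kA + 1] * (1 + 1e-7)]) / sum(pr)
  expect_equal(unname(p), p_oracle, tolerance = 1e-10)
})

test_that("filters apply the exact strict/inclusive threshold conjunction", {
  d <- data.frame(
    transcript_id = sprintf("g%d.1", 1:6), stage = "C25",
    ct_rpkm = c(5, 5, 5, 20, 10, 10),
    fp_rpkm = c(1.0, 5, 0.9, 1.5, 2, 2),
    te = c(1.2, 2.0, 1.5, 0.075, 1.0, 3),
    pvalue = c(0.04, 0.05, 0.01, 0.001, 0.01, NA))
  hi <- filter_transcripts(d, high_te_criteria(), "C25") |> suppressWarnings()
  expect_true("g1.1" %in% hi)       # FP exactly 1 is inclusive
  expect_false("g2.1" %in% hi)      # p = 0.05 fails the strict inequality
  expect_false("g3.1" %in% hi)      # FP below 1
  expect_false("g5.1" %in% hi)      # TE exactly 1 fails the strict bound
  expect_warning(filter_transcripts(d, high_te_criteria(), "C25"), "p-value")
  lo <- filter_transcripts(d, low_te_criteria(), "C25") |> suppressWarnings()
  expect_true("g4.1" %in% lo)       # TE 0.075 <= 0.1, CT 20 >= 10
  d2 <- d; d2$te[4] <- 0.1          # boundary: inclusive for low TE
  expect_true("g4.1" %in% suppressWarnings(
    filter_transcripts(d2, low_te_criteria(), "C25")))
})

test_that("relaxing any single filter threshold yields a superset", {
  set.seed(12)
  d <- data.frame(transcript_id = sprintf("g%04d.1", 1:400), stage = "C25",
                  ct_rpkm = rlnorm(400, 2, 1), fp_rpkm = rlnorm(400, 1, 1),
                  pvalue = runif(400))
  d$te <- d$fp_rpkm / d$ct_rpkm
  base <- filter_transcripts(d, high_te_criteria(), "C25")
  for (crit in list(filter_criteria(0.2, 1, "greater", "fp_rpkm", 1),
                    filter_criteria(0.05, 0.5, "greater", "fp_rpkm", 1),
                    filter_criteria(0.05, 1, "greater", "fp_rpkm", 0.2))) {
    expect_true(all(base %in% filter_transcripts(d, crit, "C25")))
  }
})

test_that("splice variants collapse to unique genes and union across stages", {
  gs <- collapse_unique_genes(list(
    C25 = c("Glyma.06G324400.2", "Glyma.06G324400.1", "Glyma.04G257100.2"),
    C100 = c("Glyma.04G257100.1"),
    C300 = character(0)))
  expect_equal(gs$per_stage$n_transcripts, c(3L, 1L, 0L))
  expect_equal(gs$per_stage$n_primary, c(2L, 1L, 0L))
  expect_equal(gs$n_union, 2L)
  expect_equal(sort(gs$union_genes), c("Glyma.04G257100", "Glyma.06G324400"))
  # malformed id passes through verbatim with a warning
  expect_warning(g <- gene_id_of("scaffold_17"), "suffix")
  expect_equal(g, "scaffold_17")
})

test_that("expressed counts and percentages match the published bookkeeping", {
  ref <- extdata("filter_summary_counts.tsv")
  pct <- percent_of_expressed(ref$high_te_primary, ref$expressed_genes)
  expect_equal(pct, c(0.91, 0.94, 0.57))
  # threshold above every RPKM yields zero expressed
  d <- data.frame(transcript_id = c("a.1", "b.1"), gene_id = c("a", "b"),
                  stage = "C25", ct_rpkm = c(3, 8))
  expect_equal(expressed_counts(d, threshold = 100)$n_transcripts, 0L)
  ec <- expressed_counts(d, threshold = 1)
  expect_equal(ec$n_transcripts, 2L)
  expect_equal(ec$n_genes, 2L)
})

test_that("the master TE table is internally consistent", {
  cfg <- tiny_config(seed = 43, reads_per_library = 6000)
  sim <- build_transcriptome(cfg)
  idx <- build_index(sim$sequences)
  libs <- simulate_all_libraries(sim)
  ex <- exclude_rdna(sim$models, lapply(libs, function(l) align_reads(l, idx)$hits))
  cm <- count_hits(ex$hits, ex$models)
  lens <- stats::setNames(ex$models$length, ex$models$transcript_id)
  te <- te_table(cm, lens)
  expect_equal(nrow(te), nrow(ex$models) * 3)
  # TE identity: the stored rounded value equals the rounded ratio
  expect_equal(te$te_round, round_half_up(te$fp_rpkm / te$ct_rpkm))
  expect_true(all(te$pvalue > 0 & te$pvalue <= 1))
  expect_true(all(te$ct_rpkm >= 0.1 & te$fp_rpkm >= 0.1))
})
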