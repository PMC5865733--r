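#' Simulation configuration for synthetic ribosome-profiling libraries
#'
#' Builds and validates the configuration object consumed by
#' [build_transcriptome()] and [simulate_library()]. The defaults emulate the
#' statistical structure of paired cotyledon footprint (FP) and fragmented
#' total-RNA control (CT) libraries: CT read lengths roughly uniform over
#' 26--28 nt, FP read lengths peaking at 31--33 nt within a 26--34 nt size
#' selection, footprints confined to the CDS apart from a small leakage
#' fraction, heavy rRNA contamination, multi-mapping paralog pairs, and
#' nuclear near-copies of organelle genes carrying very low true TE.
#'
#' @param n_genes number of nuclear protein-coding gene models (one transcript
#'   each plus any paralog duplicates).
#' @param utr5_len_range,cds_len_range,utr3_len_range integer length ranges
#'   (nt) for the three transcript regions.
#' @param n_rdna_models number of transcripts tagged as rDNA; reads drawn from
#'   them model rRNA contamination.
#' @param n_organelle_genes named integer vector: number of CDS features on
#'   each organelle genome (names are the organelle labels).
#' @param organelle_gene_len_range CDS length range (nt) for organelle genes.
#' @param organelle_copy_identities fractions in \[0,1\]; for each value one
#'   nuclear transcript carries a CDS that is an identity-f copy of a
#'   chloroplast gene.
#' @param n_paralog_pairs number of ordinary genes duplicated with an
#'   identical CDS but distinct UTRs, creating genuine multi-mapping reads.
#' @param stages ordered stage labels.
#' @param replicates biological replicates per (stage, type).
#' @param reads_per_library reads drawn per simulated library.
#' @param ct_length_dist,fp_length_dist probability weights over read lengths
#'   26--34 nt; must sum to 1. CT mode must lie in 26--28, FP mode in 31--33.
#' @param utr_leakage fraction of FP reads whose start is uniform over the
#'   whole transcript rather than confined to the CDS.
#' @param rrna_fraction expected fraction of reads drawn from rDNA models
#'   (default 0.3; the contamination observed in footprint experiments spans
#'   roughly 0.2--0.8).
#' @param error_rate per-base sequencing error rate (default 0; the
#'   downstream aligner rejects any mismatch, so errors only discard reads).
#' @param append_adapter if TRUE, the 3' linker is appended to every read so
#'   the adapter trimmer can be exercised.
#' @param adapter linker sequence appended when `append_adapter` is TRUE.
#' @param abundance_meanlog,abundance_sdlog log-normal parameters for the
#'   relative mRNA abundance of ordinary genes.
#' @param seed integer master seed; every downstream draw is derived from it.
#' @return an object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_genes = 1500,
                              utr5_len_range = c(60L, 240L),
                              cds_len_range = c(300L, 1500L),
                              utr3_len_range = c(80L, 300L),
                              n_rdna_models = 3L,
                              n_organelle_genes = c(chloroplast = 6L, mitochondrion = 4L),
                              organelle_gene_len_range = c(500L, 1200L),
                              organelle_copy_identities = c(1.0, 0.85),
                              n_paralog_pairs = 2L,
                              stages = c("C25", "C100", "C300"),
                              replicates = 2L,
                              reads_per_library = 150000L,
                              ct_length_dist = NULL,
                              fp_length_dist = NULL,
                              utr_leakage = 0.05,
                              rrna_fraction = 0.3,
                              error_rate = 0,
                              append_adapter = FALSE,
                              adapter = "CTGTAGGCACCATCAAT",
                              abundance_meanlog = log(10),
                              abundance_sdlog = 1.6,
                              seed = 1L) {
  if (is.null(ct_length_dist)) {
    ct_length_dist <- c(0.18, 0.19, 0.18, 0.11, 0.09, 0.08, 0.07, 0.05, 0.05)
  }
  if (is.null(fp_length_dist)) {
    fp_length_dist <- c(0.02, 0.03, 0.04, 0.06, 0.10, 0.17, 0.22, 0.20, 0.16)
  }
  names(ct_length_dist) <- names(fp_length_dist) <- as.character(26:34)

  chk_range <- function(r, what) {
    if (length(r) != 2L || any(r <= 0) || r[2] < r[1]) {
      stop("degenerate ", what, " length range: [", r[1], ", ", r[2], "]")
    }
    as.integer(r)
  }
  utr5_len_range <- chk_range(utr5_len_range, "5'UTR")
  cds_len_range  <- chk_range(cds_len_range, "CDS")
  utr3_len_range <- chk_range(utr3_len_range, "3'UTR")
  organelle_gene_len_range <- chk_range(organelle_gene_len_range, "organelle CDS")

  stopifnot(n_genes >= 1, n_rdna_models >= 0, replicates >= 1,
            reads_per_library >= 1, length(stages) >= 1)
  if (abs(sum(ct_length_dist) - 1) > 1e-8 || abs(sum(fp_length_dist) - 1) > 1e-8) {
    stop("read length distributions must sum to 1 over 26-34 nt")
  }
  if (!(26:34)[which.max(ct_length_dist)] %in% 26:28) {
    stop("CT length distribution must have its mode in 26-28 nt")
  }
  if (!(26:34)[which.max(fp_length_dist)] %in% 31:33) {
    stop("FP length distribution must have its mode in 31-33 nt")
  }
  if (utr_leakage < 0 || utr_leakage > 1) stop("utr_leakage must lie in [0,1]")
  if (rrna_fraction < 0 || rrna_fraction > 1) stop("rrna_fraction must lie in [0,1]")
  if (any(organelle_copy_identities < 0 | organelle_copy_identities > 1)) {
    stop("organelle_copy_identities must lie in [0,1]")
  }
  if (rrna_fraction > 0 && n_rdna_models == 0) {
    stop("rrna_fraction > 0 requires at least one rDNA model")
  }
  if (is.null(names(n_organelle_genes))) {
    stop("n_organelle_genes must be a named vector of per-organelle gene counts")
  }
  if (length(organelle_copy_identities) > 0 &&
      (!"chloroplast" %in% names(n_organelle_genes) ||
       n_organelle_genes[["chloroplast"]] < length(organelle_copy_identities))) {
    stop("need at least one chloroplast gene per requested copy identity")
  }

  structure(list(
    n_genes = as.integer(n_genes),
    utr5_len_range = utr5_len_range, cds_len_range = cds_len_range,
    utr3_len_range = utr3_len_range,
    n_rdna_models = as.integer(n_rdna_models),
    n_organelle_genes = n_organelle_genes,
    organelle_gene_len_range = organelle_gene_len_range,
    organelle_copy_identities = organelle_copy_identities,
    n_paralog_pairs = as.integer(n_paralog_pairs),
    stages = stages, replicates = as.integer(replicates),
    reads_per_library = as.integer(reads_per_library),
    ct_length_dist = ct_length_dist, fp_length_dist = fp_length_dist,
    utr_leakage = utr_leakage, rrna_fraction = rrna_fraction,
    error_rate = error_rate,
    append_adapter = isTRUE(append_adapter), adapter = adapter,
    abundance_meanlog = abundance_meanlog, abundance_sdlog = abundance_sdlog,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

.random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# copy `seq` mutating exactly round((1 - identity) * nchar) positions,
# each to a different base, so realized identity equals the request
.mutated_copy <- function(seq, identity) {
  n <- nchar(seq)
  n_mut <- round((1 - identity) * n)
  if (n_mut == 0) return(seq)
  pos <- sample.int(n, n_mut)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars[pos] <- vapply(chars[pos],
                       function(b) sample(setdiff(bases, b), 1L), "")
  paste(chars, collapse = "")
}

#' Generate a synthetic transcriptome, organelle genomes, and ground truth
#'
#' Draws a nuclear transcript set partitioned into 5'UTR/CDS/3'UTR regions,
#' rDNA-tagged models, organelle genomes with CDS features on both strands,
#' nuclear near-copies of chloroplast genes at the requested identities, and
#' the latent per-gene, per-stage abundances and true translational
#' efficiencies that [simulate_library()] samples from. Deterministic for a
#' fixed `config$seed`.
#'
#' Gene classes and their true-TE trajectories across the default stages:
#' `ordinary` TE ~ 1 throughout; `high_te_early` TE ~ 10 at the first stage
#' falling back to ~1; `low_te` TE ~ 0.05 with abundant mRNA; `storage_like`
#' TE rising ~0.4 to ~1.3 with mRNA peaking mid-development; and
#' `organelle_homolog` TE ~ 0.05. `ct_abundance` is expressed in expected
#' RPKM units (relative abundances are rescaled per stage so that expected
#' RPKM equals the stored value), and the abundance-weighted mean TE is
#' normalized to 1 per stage so that the TE estimator is unbiased for
#' `te_true` (the TE statistic is only identified up to a global
#' library-depth factor).
#'
#' @param config a [simulation_config()].
#' @return a list of class `ribote_sim` with elements `sequences` (named
#'   character vector of transcript sequences), `models` (transcript model
#'   data frame: transcript_id, gene_id, length, cds_start/cds_end 0-based
#'   half-open, is_rdna), `organelles` (per-organelle genome string plus CDS
#'   feature table with strand), `truth` (gene x stage: ct_abundance, te_true,
#'   class) and `config`.
#' @export
build_transcriptome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)

  ## --- organelle genomes -------------------------------------------------
  organelles <- list()
  for (org in names(config$n_organelle_genes)) {
    n_org <- config$n_organelle_genes[[org]]
    if (n_org == 0) { next }
    lens <- sample(config$organelle_gene_len_range[1]:config$organelle_gene_len_range[2],
                   n_org, replace = TRUE)
    cds_seqs <- vapply(lens, .random_seq, "")
    spacers <- vapply(rep(200L, n_org + 1L), .random_seq, "")
    strands <- rep(c("+", "-"), length.out = n_org)
    genome <- spacers[1]
    starts <- integer(n_org)
    for (i in seq_len(n_org)) {
      placed <- if (strands[i] == "+") cds_seqs[i] else .revcomp(cds_seqs[i])
      starts[i] <- nchar(genome) + 1L
      genome <- paste0(genome, placed, spacers[i + 1L])
    }
    cds <- data.frame(
      cds_id = sprintf("%s_gene_%02d", org, seq_len(n_org)),
      start = starts, end = starts + lens - 1L, strand = strands,
      length = lens, stringsAsFactors = FALSE
    )
    organelles[[org]] <- list(genome = genome, cds = cds,
                              cds_seq = stats::setNames(cds_seqs, cds$cds_id))
  }

  ## --- nuclear gene classes ----------------------------------------------
  n <- config$n_genes
  n_org_copy <- length(config$organelle_copy_identities)
  n_high <- max(1L, round(0.08 * n))
  n_low <- max(1L, round(0.10 * n))
  n_storage <- max(1L, round(0.06 * n))
  if (n_org_copy + n_high + n_low + n_storage > n) {
    stop("n_genes too small for the requested class structure")
  }
  class <- rep("ordinary", n)
  class[seq_len(n_org_copy)] <- "organelle_homolog"
  class[n_org_copy + seq_len(n_high)] <- "high_te_early"
  class[n_org_copy + n_high + seq_len(n_low)] <- "low_te"
  class[n_org_copy + n_high + n_low + seq_len(n_storage)] <- "storage_like"

  ## --- transcript structures ---------------------------------------------
  utr5 <- sample(config$utr5_len_range[1]:config$utr5_len_range[2], n, TRUE)
  cdsl <- sample(config$cds_len_range[1]:config$cds_len_range[2], n, TRUE)
  utr3 <- sample(config$utr3_len_range[1]:config$utr3_len_range[2], n, TRUE)

  gene_ids <- sprintf("Gene.%04d", seq_len(n))
  tx_ids <- paste0(gene_ids, ".1")

  ## organelle-transfer gene models are essentially inserted coding
  ## fragments; their annotated UTRs are minimal
  is_org <- class == "organelle_homolog"
  utr5[is_org] <- sample(30:80, sum(is_org), TRUE)
  utr3[is_org] <- sample(30:80, sum(is_org), TRUE)

  cds_seq <- character(n)
  org_source <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (class[i] == "organelle_homolog") {
      src <- organelles[["chloroplast"]]$cds[i, ]   # one chloroplast gene each
      ident <- config$organelle_copy_identities[i]
      cds_seq[i] <- .mutated_copy(organelles[["chloroplast"]]$cds_seq[[i]], ident)
      cdsl[i] <- nchar(cds_seq[i])
      org_source[i] <- src$cds_id
    } else {
      cds_seq[i] <- .random_seq(cdsl[i])
    }
  }
  utr5_seq <- vapply(utr5, .random_seq, "")
  utr3_seq <- vapply(utr3, .random_seq, "")

  ## paralog pairs: duplicate the CDS of the last ordinary genes
  if (config$n_paralog_pairs > 0) {
    ord_idx <- which(class == "ordinary")
    src <- utils::tail(ord_idx, config$n_paralog_pairs)
    for (j in seq_along(src)) {
      i <- src[j]
      gene_ids <- c(gene_ids, sprintf("Gene.%04d", n + j))
      tx_ids <- c(tx_ids, sprintf("Gene.%04d.1", n + j))
      class <- c(class, "ordinary")
      utr5 <- c(utr5, sample(config$utr5_len_range[1]:config$utr5_len_range[2], 1L))
      utr3 <- c(utr3, sample(config$utr3_len_range[1]:config$utr3_len_range[2], 1L))
      cdsl <- c(cdsl, cdsl[i])
      cds_seq <- c(cds_seq, cds_seq[i])
      utr5_seq <- c(utr5_seq, .random_seq(utr5[length(utr5)]))
      utr3_seq <- c(utr3_seq, .random_seq(utr3[length(utr3)]))
      org_source <- c(org_source, NA_character_)
    }
  }
  n_all <- length(tx_ids)

  ## rDNA models (ordinary random sequences tagged by ID)
  if (config$n_rdna_models > 0) {
    r_cds <- sample(config$cds_len_range[1]:config$cds_len_range[2],
                    config$n_rdna_models, TRUE)
    r5 <- sample(config$utr5_len_range[1]:config$utr5_len_range[2],
                 config$n_rdna_models, TRUE)
    r3 <- sample(config$utr3_len_range[1]:config$utr3_len_range[2],
                 config$n_rdna_models, TRUE)
    gene_ids <- c(gene_ids, sprintf("rDNA.%04d", seq_len(config$n_rdna_models)))
    tx_ids <- c(tx_ids, sprintf("rDNA.%04d.1", seq_len(config$n_rdna_models)))
    class <- c(class, rep("rdna", config$n_rdna_models))
    utr5 <- c(utr5, r5); cdsl <- c(cdsl, r_cds); utr3 <- c(utr3, r3)
    utr5_seq <- c(utr5_seq, vapply(r5, .random_seq, ""))
    cds_seq <- c(cds_seq, vapply(r_cds, .random_seq, ""))
    utr3_seq <- c(utr3_seq, vapply(r3, .random_seq, ""))
    org_source <- c(org_source, rep(NA_character_, config$n_rdna_models))
  }

  sequences <- stats::setNames(paste0(utr5_seq, cds_seq, utr3_seq), tx_ids)
  models <- data.frame(
    transcript_id = tx_ids,
    gene_id = gene_ids,
    length = utr5 + cdsl + utr3,
    cds_start = utr5,                 # 0-based half-open [cds_start, cds_end)
    cds_end = utr5 + cdsl,
    is_rdna = class == "rdna",
    class = class,
    organelle_source = org_source,
    stringsAsFactors = FALSE
  )

  ## --- latent abundances and TE trajectories ------------------------------
  n_stage <- length(config$stages)
  coding <- models$class != "rdna"
  nc <- sum(coding)
  base_abund <- numeric(nc)
  cls <- models$class[coding]
  base_abund[cls == "ordinary"] <- stats::rlnorm(sum(cls == "ordinary"),
                                                 config$abundance_meanlog,
                                                 config$abundance_sdlog)
  base_abund[cls == "high_te_early"] <- stats::rlnorm(sum(cls == "high_te_early"),
                                                      log(150), 0.8)
  base_abund[cls == "low_te"] <- stats::rlnorm(sum(cls == "low_te"), log(200), 0.6)
  base_abund[cls == "storage_like"] <- stats::rlnorm(sum(cls == "storage_like"),
                                                     log(400), 0.6)
  base_abund[cls == "organelle_homolog"] <- stats::rlnorm(sum(cls == "organelle_homolog"),
                                                          log(200), 0.5)

  stage_mult <- matrix(1, nc, n_stage)
  te <- matrix(1, nc, n_stage)
  jit <- function(k, s = 0.15) stats::rlnorm(k, 0, s)
  for (s in seq_len(n_stage)) {
    frac <- if (n_stage > 1) (s - 1) / (n_stage - 1) else 0
    k <- sum(cls == "ordinary")
    te[cls == "ordinary", s] <- jit(k, 0.25)
    k <- sum(cls == "high_te_early")
    te[cls == "high_te_early", s] <- c(18, 1.2, 0.8)[min(s, 3)] * jit(k, 0.5)
    k <- sum(cls == "low_te")
    te[cls == "low_te", s] <- 0.05 * jit(k)
    k <- sum(cls == "storage_like")
    te[cls == "storage_like", s] <- (0.4 + (1.3 - 0.4) * frac) * jit(k)
    stage_mult[cls == "storage_like", s] <- c(0.4, 1.0, 0.8)[min(s, 3)]
    k <- sum(cls == "organelle_homolog")
    te[cls == "organelle_homolog", s] <- 0.05 * jit(k)
  }

  L <- models$length[coding]
  truth_list <- vector("list", n_stage)
  for (s in seq_len(n_stage)) {
    a_raw <- base_abund * stage_mult[, s]
    a_rpkm <- a_raw * 1e9 / sum(a_raw * L)          # expected control RPKM
    te_s <- te[, s] * sum(a_raw * L) / sum(te[, s] * a_raw * L)
    truth_list[[s]] <- data.frame(
      transcript_id = models$transcript_id[coding],
      gene_id = models$gene_id[coding],
      stage = config$stages[s],
      ct_abundance = a_rpkm,
      te_true = te_s,
      class = cls,
      stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, truth_list)
  rownames(truth) <- NULL

  structure(list(sequences = sequences, models = models,
                 organelles = organelles, truth = truth, config = config),
            class = "ribote_sim")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate one sequencing library
#'
#' Draws `config$reads_per_library` reads for one (stage, type, replicate)
#' library. Reads are exact substrings of their source transcripts (matching
#' the zero-mismatch alignment policy) unless `config$error_rate > 0`. An
#' `rrna_fraction` share of reads (binomially drawn) comes from the rDNA
#' models; the remainder is sampled with probability proportional to
#' `ct_abundance * length` for CT libraries and `te_true * ct_abundance *
#' length` for FP libraries. CT start positions are uniform over the
#' transcript; FP starts are uniform over CDS positions apart from a
#' `utr_leakage` fraction uniform over the whole transcript. Read lengths
#' follow the type-specific 26--34 nt distribution. Deterministic for fixed
#' (seed, stage, type, replicate).
#'
#' @param sim a `ribote_sim` from [build_transcriptome()].
#' @param library_type "CT" or "FP".
#' @param stage stage label present in `sim$config$stages`.
#' @param replicate replicate index (1-based).
#' @return data frame with columns read_id, sequence, source_id (true source
#'   transcript), start (0-based on the source) and length.
#' @export
simulate_library <- function(sim, library_type = c("CT", "FP"), stage,
                             replicate = 1L) {
  stopifnot(inherits(sim, "ribote_sim"))
  library_type <- match.arg(library_type)
  config <- sim$config
  stage_i <- match(stage, config$stages)
  if (is.na(stage_i)) stop("unknown stage: ", stage)
  if (replicate < 1 || replicate > config$replicates) {
    stop("replicate out of range: ", replicate)
  }
  models <- sim$models
  min_tx_len <- min(models$length)
  if (min_tx_len < 34L) stop("requested reads exceed representable depth: a transcript is shorter than the longest read")

  set.seed(.library_seed(config$seed, stage_i, library_type, replicate))

  N <- config$reads_per_library
  n_rrna <- if (config$n_rdna_models > 0) stats::rbinom(1L, N, config$rrna_fraction) else 0L
  n_sig <- N - n_rrna

  truth_s <- sim$truth[sim$truth$stage == stage, ]
  tx_idx <- match(truth_s$transcript_id, models$transcript_id)
  L <- models$length[tx_idx]
  w <- if (library_type == "CT") truth_s$ct_abundance * L else
    truth_s$te_true * truth_s$ct_abundance * L

  len_dist <- if (library_type == "CT") config$ct_length_dist else config$fp_length_dist
  lens_all <- 26:34

  draw_reads <- function(k, src_rows, weights, fp_positional) {
    if (k == 0L) {
      return(data.frame(source_id = character(0), start = integer(0),
                        length = integer(0), sequence = character(0),
                        stringsAsFactors = FALSE))
    }
    pick <- sample.int(length(src_rows), k, replace = TRUE, prob = weights)
    ti <- src_rows[pick]
    rl <- sample(lens_all, k, replace = TRUE, prob = len_dist)
    tl <- models$length[ti]
    a <- models$cds_start[ti]; b <- models$cds_end[ti]
    if (fp_positional) {
      leak <- stats::runif(k) < config$utr_leakage
      lo <- ifelse(leak, 0L, a)
      hi <- ifelse(leak, tl - rl, pmax(lo, b - rl))
      # CDS shorter than the read (cannot happen with default ranges) falls
      # back to a start clamped inside the transcript
      hi <- pmin(hi, tl - rl)
    } else {
      lo <- 0L
      hi <- tl - rl
    }
    start <- lo + floor(stats::runif(k) * (hi - lo + 1L))
    seqs <- substr(sim$sequences[models$transcript_id[ti]], start + 1L, start + rl)
    data.frame(source_id = models$transcript_id[ti], start = as.integer(start),
               length = rl, sequence = unname(seqs), stringsAsFactors = FALSE)
  }

  sig <- draw_reads(n_sig, tx_idx, w, library_type == "FP")
  rdna_rows <- which(models$is_rdna)
  rr <- draw_reads(n_rrna, rdna_rows, rep(1, length(rdna_rows)), FALSE)
  reads <- rbind(sig, rr)

  if (config$error_rate > 0) {
    n_err <- stats::rbinom(nrow(reads), reads$length, config$error_rate)
    for (i in which(n_err > 0)) {
      reads$sequence[i] <- .mutated_copy(reads$sequence[i],
                                         1 - n_err[i] / reads$length[i])
    }
  }
  if (config$append_adapter) {
    reads$sequence <- paste0(reads$sequence, config$adapter)
  }
  reads$read_id <- sprintf("%s%s_rep%d_%07d|%s", stage, library_type,
                           replicate, seq_len(nrow(reads)), reads$source_id)
  reads[, c("read_id", "sequence", "source_id", "start", "length")]
}

#' Simulate all libraries of an experiment
#'
#' Convenience wrapper calling [simulate_library()] for every
#' (stage, type, replicate) combination of the configuration.
#'
#' @param sim a `ribote_sim`.
#' @return named list of read data frames, keyed `<stage><type>_rep<i>`.
#' @export
simulate_all_libraries <- function(sim) {
  config <- sim$config
  out <- list()
  for (stage in config$stages) {
    for (type in c("CT", "FP")) {
      for (rep_i in seq_len(config$replicates)) {
        key <- sprintf("%s%s_rep%d", stage, type, rep_i)
        out[[key]] <- simulate_library(sim, type, stage, rep_i)
      }
    }
  }
  out
}
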