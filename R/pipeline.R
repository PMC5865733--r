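#' Trim the 3' sequencing adapter from reads
#'
#' Truncates each read at the first exact occurrence of the adapter: either
#' the full adapter anywhere in the read, or a >= 6 nt prefix of the adapter
#' at the read's 3' end (the signature of an insert longer than the part of
#' the adapter sequenced). Trimming is exact-match only, consistent with the
#' zero-mismatch alignment downstream; reads shorter than `min_len` after
#' trimming are dropped and counted.
#'
#' @param reads read data frame (read_id, sequence).
#' @param adapter adapter sequence (default the footprint-library 3'
#'   linker CTGTAGGCACCATCAAT).
#' @param min_len minimum retained insert length (default 20).
#' @return list with `reads` (trimmed, short reads dropped) and `summary`
#'   (n_input, n_trimmed, n_dropped_short, n_output).
#' @export
trim_adapter <- function(reads, adapter = "CTGTAGGCACCATCAAT", min_len = 20L) {
  if (nchar(adapter) == 0) stop("adapter must be nonempty")
  seqs <- reads$sequence
  n <- length(seqs)
  cut <- rep(NA_integer_, n)
  # full internal (or terminal) match
  pos <- regexpr(adapter, seqs, fixed = TRUE)
  cut[pos > 0] <- pos[pos > 0] - 1L
  # 3'-end partial match to an adapter prefix (>= 6 nt), longest first
  todo <- which(is.na(cut))
  for (w in seq(min(nchar(adapter) - 1L, 34L), 6L)) {
    if (length(todo) == 0L) break
    suff_hit <- endsWith(seqs[todo], substr(adapter, 1L, w))
    cut[todo[suff_hit]] <- nchar(seqs[todo[suff_hit]]) - w
    todo <- todo[!suff_hit]
  }
  trimmed <- !is.na(cut)
  out_seq <- ifelse(trimmed, substr(seqs, 1L, ifelse(is.na(cut), 0L, cut)), seqs)
  keep <- nchar(out_seq) >= min_len
  out <- reads
  out$sequence <- out_seq
  out <- out[keep, , drop = FALSE]
  list(reads = out,
       summary = c(n_input = n, n_trimmed = sum(trimmed),
                   n_dropped_short = sum(!keep), n_output = sum(keep)))
}

#' Pipeline configuration with the conventional defaults
#'
#' Every analysis parameter defaults to the standard setting of the method:
#' a multi-mapping cap of 25 with zero mismatches, an RPKM floor of 0.1, an
#' expressed cut-off of 1 RPKM, the high-TE rule (p < 0.05, TE > 1,
#' FP RPKM >= 1) and low-TE rule (p < 0.05, TE <= 0.1, CT RPKM >= 10).
#'
#' @param sim a [simulation_config()] describing the input libraries.
#' @param output_dir where stage outputs are written.
#' @param max_multimap,mismatches aligner settings.
#' @param kmer index seed length.
#' @param rpkm_floor reporting floor applied before TE.
#' @param expressed_threshold expressed-transcript RPKM cut-off.
#' @param high_criteria,low_criteria [filter_criteria()] objects.
#' @param n_clusters k for TE-trajectory clustering.
#' @param cluster_seed seed for the centroid draw.
#' @param write_reads also write per-library FASTQ files (off by default;
#'   [write_fixture()] serves that purpose).
#' @param flag_organelles run organelle homology flagging and chloroplast
#'   profiling.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            output_dir = tempfile("ribote_run_"),
                            max_multimap = 25L, mismatches = 0L,
                            kmer = 20L, rpkm_floor = 0.1,
                            expressed_threshold = 1,
                            high_criteria = high_te_criteria(),
                            low_criteria = low_te_criteria(),
                            n_clusters = 4L, cluster_seed = 1L,
                            write_reads = FALSE, flag_organelles = TRUE) {
  structure(list(sim = sim, output_dir = output_dir,
                 max_multimap = as.integer(max_multimap),
                 mismatches = as.integer(mismatches), kmer = as.integer(kmer),
                 rpkm_floor = rpkm_floor,
                 expressed_threshold = expressed_threshold,
                 high_criteria = high_criteria, low_criteria = low_criteria,
                 n_clusters = as.integer(n_clusters),
                 cluster_seed = as.integer(cluster_seed),
                 write_reads = isTRUE(write_reads),
                 flag_organelles = isTRUE(flag_organelles)),
            class = "pipeline_config")
}

.tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on a simulated experiment
#'
#' Executes simulate -> trim -> align -> rDNA-exclude -> count -> RPKM ->
#' TE + NB test -> high/low filters -> cluster -> organelle profiling,
#' writing per-stage TSV outputs, a read-accounting log, and a run manifest
#' with parameters and checksums. Idempotent for a fixed seed.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with all in-memory stage results: `sim`,
#'   `counts`, `te_results`, `high`/`low` gene sets, `expressed`,
#'   `summary_table`, `clusters`, `organelle_flags`, `chloro_profile`,
#'   `log`, `manifest_path`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  logs <- list()
  note <- function(step, library, metric, value) {
    logs[[length(logs) + 1L]] <<- data.frame(step = step, library = library,
                                             metric = metric, value = value,
                                             stringsAsFactors = FALSE)
  }

  ## 1. simulate
  sim <- build_transcriptome(config$sim)
  libraries <- simulate_all_libraries(sim)
  for (key in names(libraries)) note("simulate", key, "reads", nrow(libraries[[key]]))

  ## 2. trim (only needed when the simulator appended the linker)
  if (config$sim$append_adapter) {
    for (key in names(libraries)) {
      tr <- trim_adapter(libraries[[key]])
      libraries[[key]] <- tr$reads
      note("trim", key, "trimmed", tr$summary[["n_trimmed"]])
      note("trim", key, "dropped_short", tr$summary[["n_dropped_short"]])
    }
  }
  if (config$write_reads) {
    rd <- file.path(config$output_dir, "reads")
    dir.create(rd, showWarnings = FALSE)
    for (key in names(libraries)) {
      write_reads_fastq(libraries[[key]], file.path(rd, paste0(key, ".fastq")))
    }
  }

  ## 3. align
  idx <- build_index(sim$sequences, k = config$kmer)
  hit_list <- list()
  for (key in names(libraries)) {
    al <- align_reads(libraries[[key]], idx,
                      max_multimap = config$max_multimap,
                      mismatches_allowed = config$mismatches)
    hit_list[[key]] <- al$hits
    for (metric in names(al$summary)) note("align", key, metric, al$summary[[metric]])
  }

  ## 4. rDNA exclusion
  before <- vapply(hit_list, nrow, 0L)
  ex <- exclude_rdna(sim$models, hit_list)
  hit_list <- ex$hits
  models <- ex$models
  after <- vapply(hit_list, nrow, 0L)
  for (key in names(hit_list)) {
    note("exclude_rdna", key, "rdna_hits_removed", before[[key]] - after[[key]])
    note("exclude_rdna", key, "retained_hits", after[[key]])
  }
  note("exclude_rdna", "-", "rdna_models_removed", ex$removed_models)
  note("exclude_rdna", "-", "retained_models", nrow(models))

  ## 5. count + region coverage
  counts <- count_hits(hit_list, models)
  lengths <- stats::setNames(models$length, models$transcript_id)
  .tsv(data.frame(transcript_id = rownames(counts$counts), counts$counts,
                  check.names = FALSE),
       file.path(config$output_dir, "counts.tsv"))

  regc <- region_counts(hit_list, models)
  ## per-stage CT/FP region ratio rows (replicates summed, as for a single
  ## deeply sequenced pair)
  regc$stage <- .parse_library_key(regc$library)$stage
  regc$type <- .parse_library_key(regc$library)$type
  agg <- stats::aggregate(cbind(utr5, cds, utr3) ~ transcript_id + stage + type,
                          data = regc, FUN = sum)
  ratio_rows <- list()
  for (s in unique(agg$stage)) {
    ct <- agg[agg$stage == s & agg$type == "CT", ]
    fp <- agg[agg$stage == s & agg$type == "FP", ]
    common <- intersect(ct$transcript_id, fp$transcript_id)
    for (tx in common) {
      ctc <- ct[ct$transcript_id == tx, c("utr5", "cds", "utr3")]
      fpc <- fp[fp$transcript_id == tx, c("utr5", "cds", "utr3")]
      rr <- region_ratio_table(ctc, fpc)
      names(ctc) <- paste0("ct_", names(ctc))
      names(fpc) <- paste0("fp_", names(fpc))
      ratio_rows[[length(ratio_rows) + 1L]] <-
        cbind(data.frame(transcript_id = tx, stage = s, row.names = NULL),
              ctc, fpc, rr)
    }
  }
  region_table <- do.call(rbind, ratio_rows)
  .tsv(region_table, file.path(config$output_dir, "region_ratios.tsv"))

  ## 6. TE + test
  te_results <- te_table(counts, lengths, floor_value = config$rpkm_floor)
  .tsv(te_results, file.path(config$output_dir, "te_results.tsv"))

  ## 7. filters
  stages <- config$sim$stages
  high_sets <- lapply(stages, function(s)
    filter_transcripts(te_results, config$high_criteria, s))
  names(high_sets) <- stages
  low_sets <- lapply(stages, function(s)
    filter_transcripts(te_results, config$low_criteria, s))
  names(low_sets) <- stages
  high <- collapse_unique_genes(high_sets)
  low <- collapse_unique_genes(low_sets)
  expressed <- expressed_counts(te_results, config$expressed_threshold)
  summary_table <- report_summary(high, low, expressed)
  .tsv(summary_table, file.path(config$output_dir, "summary.tsv"))

  ## 8. clustering of high-TE trajectories
  clusters <- NULL
  union_high <- unique(unlist(high_sets, use.names = FALSE))
  if (length(union_high) > config$n_clusters) {
    prof <- matrix(NA_real_, length(union_high), length(stages),
                   dimnames = list(union_high, stages))
    for (s in stages) {
      d <- te_results[te_results$stage == s, ]
      prof[, s] <- d$te[match(union_high, d$transcript_id)]
    }
    pf <- drop_flat_profiles(prof)
    if (nrow(pf$mat) > config$n_clusters) {
      clusters <- kmeans_cluster(pf$mat, config$n_clusters,
                                 seed = config$cluster_seed)
      memb <- data.frame(transcript_id = names(clusters$labels),
                         cluster = unname(clusters$labels),
                         pf$mat, check.names = FALSE)
      .tsv(memb, file.path(config$output_dir, "clusters_high.tsv"))
    }
  }

  ## 9. organelle homology of the low-TE set + chloroplast profiling
  organelle_flags <- NULL
  chloro_profile <- NULL
  if (config$flag_organelles && length(sim$organelles) > 0) {
    union_low <- unique(unlist(low_sets, use.names = FALSE))
    if (length(union_low) > 0) {
      mi <- match(union_low, models$transcript_id)
      cds_seqs <- stats::setNames(
        substr(sim$sequences[union_low], models$cds_start[mi] + 1L,
               models$cds_end[mi]),
        models$gene_id[mi])
      genomes <- vapply(sim$organelles, function(o) o$genome, "")
      organelle_flags <- flag_organelle_homology(cds_seqs, genomes)
      .tsv(organelle_flags, file.path(config$output_dir, "organelle_flags.tsv"))
    }
    if ("chloroplast" %in% names(sim$organelles)) {
      cp <- sim$organelles$chloroplast
      chloro_profile <- chloroplast_profile(
        libraries, extract_cds(cp$genome, cp$cds),
        nuclear_total_mapped = counts$total_mapped,
        floor_value = config$rpkm_floor,
        max_multimap = config$max_multimap, k = config$kmer)
      .tsv(chloro_profile, file.path(config$output_dir, "chloroplast_profile.tsv"))
    }
  }

  log_df <- do.call(rbind, logs)
  .tsv(log_df, file.path(config$output_dir, "log.tsv"))

  manifest_path <- file.path(config$output_dir, "manifest.yaml")
  outputs <- list.files(config$output_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    seed = config$sim$seed,
    parameters = list(
      n_genes = config$sim$n_genes,
      reads_per_library = config$sim$reads_per_library,
      rrna_fraction = config$sim$rrna_fraction,
      utr_leakage = config$sim$utr_leakage,
      max_multimap = config$max_multimap, mismatches = config$mismatches,
      rpkm_floor = config$rpkm_floor,
      expressed_threshold = config$expressed_threshold,
      n_clusters = config$n_clusters),
    checksums = as.list(tools::md5sum(outputs))
  )
  yaml::write_yaml(manifest, manifest_path)

  invisible(list(sim = sim, libraries = libraries, counts = counts,
                 region_table = region_table, te_results = te_results,
                 high_sets = high_sets, low_sets = low_sets,
                 high = high, low = low, expressed = expressed,
                 summary_table = summary_table, clusters = clusters,
                 organelle_flags = organelle_flags,
                 chloro_profile = chloro_profile,
                 log = log_df, manifest_path = manifest_path))
}

#' Summary table of filter results (the Table-3 shape)
#'
#' Per stage: passing transcript and primary-transcript (distinct gene)
#' counts for the high- and low-TE rules, the expressed-transcript
#' denominators, the cross-stage unique-gene unions, and the percentage of
#' expressed genes captured by each rule.
#'
#' @param high,low `gene_set` objects from [collapse_unique_genes()].
#' @param expressed data frame from [expressed_counts()].
#' @return data frame: category, stage, n_transcripts, n_primary,
#'   n_union_genes, pct_of_expressed.
#' @export
report_summary <- function(high, low, expressed) {
  one <- function(gs, label) {
    d <- gs$per_stage
    exp_n <- expressed$n_genes[match(d$stage, expressed$stage)]
    data.frame(category = label, stage = d$stage,
               n_transcripts = d$n_transcripts, n_primary = d$n_primary,
               n_union_genes = gs$n_union,
               pct_of_expressed = percent_of_expressed(d$n_primary, exp_n),
               stringsAsFactors = FALSE)
  }
  rbind(one(high, "high_te"), one(low, "low_te"),
        data.frame(category = "expressed", stage = expressed$stage,
                   n_transcripts = expressed$n_transcripts,
                   n_primary = expressed$n_genes,
                   n_union_genes = NA_integer_,
                   pct_of_expressed = NA_real_,
                   stringsAsFactors = FALSE))
}
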