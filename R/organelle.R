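#' Verdict from per-organelle identity and coverage
#'
#' A nuclear coding sequence is flagged against an organelle genome when it
#' reaches at least `min_identity` identity over at least `min_coverage` of
#' its CDS length (both thresholds inclusive). With hits to several
#' organelles the verdict is "both"; with none, "neither".
#'
#' @param identity named numeric vector (per organelle) of identity
#'   fractions.
#' @param coverage named numeric vector (same names) of CDS coverage
#'   fractions.
#' @param min_identity identity threshold (default 0.90, inclusive).
#' @param min_coverage coverage threshold (default 0.75, inclusive).
#' @return character verdict: one organelle name, "both", or "neither".
#' @export
organelle_verdict <- function(identity, coverage,
                              min_identity = 0.90, min_coverage = 0.75) {
  pass <- names(identity)[identity >= min_identity & coverage >= min_coverage]
  if (length(pass) == 0L) "neither"
  else if (length(pass) == 1L) pass
  else "both"
}

# best local alignment of a CDS against one genome, both strands
.best_local <- function(cds_seq, genome) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  p <- Biostrings::DNAString(cds_seq)
  best <- NULL
  for (subj in c(genome, .revcomp(genome))) {
    aln <- Biostrings::pairwiseAlignment(p, Biostrings::DNAString(subj),
                                         type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 2.5)
    if (is.null(best) || Biostrings::score(aln) > Biostrings::score(best)) {
      best <- aln
    }
  }
  cols <- nchar(as.character(Biostrings::pattern(best)))   # incl. gap columns
  if (cols == 0L) return(c(identity = 0, coverage = 0))
  matches <- Biostrings::nmatch(best)
  pr <- Biostrings::pattern(best)
  aligned_bases <- Biostrings::end(pr) - Biostrings::start(pr) + 1L
  c(identity = matches / cols, coverage = aligned_bases / nchar(cds_seq))
}

#' Flag nuclear coding sequences with organelle-genome homology
#'
#' For each gene's CDS, finds the best local alignment (match +1, mismatch
#' -2, gap -2.5 per base) against each organelle genome, searching both
#' strands. Identity is matches over alignment columns (gaps included);
#' coverage is aligned CDS bases over CDS length. The verdict applies the
#' inclusive >= 90 % identity over >= 75 % of CDS length rule.
#'
#' @param cds_seqs named character vector of nuclear CDS sequences.
#' @param organelle_genomes named character vector (or named list) of
#'   organelle genome sequences.
#' @param min_identity,min_coverage inclusive thresholds (defaults 0.90 and
#'   0.75).
#' @param anchor_k exact k-mer length of the seed screen (default 20).
#' @return data frame: gene_id, `<organelle>_identity` and
#'   `<organelle>_coverage` columns, verdict.
#' @export
flag_organelle_homology <- function(cds_seqs, organelle_genomes,
                                    min_identity = 0.90, min_coverage = 0.75,
                                    anchor_k = 20L) {
  organelle_genomes <- unlist(organelle_genomes)
  orgs <- names(organelle_genomes)
  if (is.null(orgs)) stop("organelle genomes must be named")
  # seed screen: a candidate must share at least one exact k-mer with the
  # genome (either strand) before the gapped extension is attempted; at 90 %
  # identity exact 20-mers are abundant, while unrelated sequences share none
  anchor_sets <- lapply(orgs, function(org) {
    g <- organelle_genomes[[org]]
    kmers <- function(s) {
      n <- nchar(s) - anchor_k + 1L
      if (n < 1L) character(0) else substring(s, 1:n, anchor_k:nchar(s))
    }
    unique(c(kmers(g), kmers(.revcomp(g))))
  })
  names(anchor_sets) <- orgs
  rows <- lapply(seq_along(cds_seqs), function(i) {
    ident <- cov <- stats::setNames(numeric(length(orgs)), orgs)
    n <- nchar(cds_seqs[[i]]) - anchor_k + 1L
    cds_kmers <- if (n < 1L) character(0) else
      substring(cds_seqs[[i]], 1:n, anchor_k:nchar(cds_seqs[[i]]))
    for (org in orgs) {
      if (!any(cds_kmers %in% anchor_sets[[org]])) next   # identity 0, coverage 0
      sc <- .best_local(cds_seqs[[i]], organelle_genomes[[org]])
      ident[org] <- sc[["identity"]]
      cov[org] <- sc[["coverage"]]
    }
    row <- data.frame(gene_id = names(cds_seqs)[i], stringsAsFactors = FALSE)
    for (org in orgs) {
      row[[paste0(org, "_identity")]] <- ident[org]
      row[[paste0(org, "_coverage")]] <- cov[org]
    }
    row$verdict <- organelle_verdict(ident, cov, min_identity, min_coverage)
    row
  })
  do.call(rbind, rows)
}

#' Extract organelle CDS sequences (strand-aware)
#'
#' @param genome organelle genome sequence (character scalar).
#' @param cds CDS feature table with start/end (1-based inclusive) and
#'   strand columns, plus a `cds_id` column.
#' @return named character vector of CDS sequences (minus-strand features
#'   reverse-complemented).
#' @export
extract_cds <- function(genome, cds) {
  seqs <- substr(rep(genome, nrow(cds)), cds$start, cds$end)
  minus <- cds$strand == "-"
  if (any(minus)) seqs[minus] <- vapply(seqs[minus], .revcomp, "")
  stats::setNames(seqs, cds$cds_id)
}

#' TE profile over organelle (chloroplast) coding sequences
#'
#' Aligns each library's reads to the organelle CDS sequences with the same
#' exact-match engine used for the nuclear models, then normalizes counts to
#' RPKM using the *nuclear* per-library mapped totals (not the
#' organelle-mapped totals), averages replicates with the usual floor, and
#' computes TE per CDS per stage.
#'
#' @param read_list named list of read data frames keyed
#'   `<stage><type>_rep<i>`.
#' @param cds_seqs named character vector of organelle CDS sequences (see
#'   [extract_cds()]).
#' @param nuclear_total_mapped named numeric vector of nuclear mapped-read
#'   totals, one per library key.
#' @param floor_value RPKM floor before TE (default 0.1).
#' @param max_multimap multi-mapping cap forwarded to [align_reads()].
#' @param k index seed length.
#' @return data frame: cds_id, stage, ct_rpkm, fp_rpkm, te, te_round.
#' @export
chloroplast_profile <- function(read_list, cds_seqs, nuclear_total_mapped,
                                floor_value = 0.1, max_multimap = 25L,
                                k = 20L) {
  miss <- setdiff(names(read_list), names(nuclear_total_mapped))
  if (length(miss) > 0) {
    stop("missing nuclear mapped totals for: ", paste(miss, collapse = ", "))
  }
  if (any(nuclear_total_mapped[names(read_list)] <= 0)) {
    stop("nuclear mapped totals must be positive")
  }
  idx <- build_index(cds_seqs, k = k)
  L <- nchar(cds_seqs)
  libs <- .parse_library_key(names(read_list))
  counts <- matrix(0L, length(cds_seqs), length(read_list),
                   dimnames = list(names(cds_seqs), names(read_list)))
  for (j in seq_along(read_list)) {
    al <- align_reads(read_list[[j]], idx, max_multimap = max_multimap)
    if (nrow(al$hits) > 0) {
      tb <- table(factor(al$hits$transcript_id, levels = names(cds_seqs)))
      counts[, j] <- as.integer(tb)
    }
  }
  r <- sweep(counts * 1e9 / L, 2L,
             nuclear_total_mapped[colnames(counts)], "/")
  avg <- average_replicates(r, libs, floor_value = floor_value,
                            apply_floor = TRUE)
  out <- list()
  for (s in avg$stages) {
    ctr <- avg$rep_avg[, paste(s, "CT", sep = "_")]
    fpr <- avg$rep_avg[, paste(s, "FP", sep = "_")]
    te <- compute_te(ctr, fpr)
    out[[s]] <- data.frame(cds_id = names(cds_seqs), stage = s,
                           ct_rpkm = unname(ctr), fp_rpkm = unname(fpr),
                           te = te$te, te_round = te$te_round,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
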