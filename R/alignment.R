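#' Build an exact-match substring index over a transcript set
#'
#' Indexes every k-mer of every transcript so that all exact full-length
#' occurrences of a read of at least `k` nt can be located: the read's first
#' k-mer is looked up and each candidate position is verified against the
#' full read. `k` must not exceed the shortest read you intend to align
#' (default 20, below the 26 nt lower end of the size selection).
#'
#' @param sequences named character vector of transcript sequences.
#' @param k seed length (default 20).
#' @return an object of class `ribote_index`.
#' @export
build_index <- function(sequences, k = 20L) {
  k <- as.integer(k)
  if (anyDuplicated(names(sequences))) stop("duplicate transcript ids in index input")
  lens <- nchar(sequences)
  usable <- which(lens >= k)
  if (length(sequences) == 0L || length(usable) == 0L) {
    tab <- data.table::data.table(kmer = character(0), tid = integer(0),
                                  pos = integer(0))
  } else {
    parts <- vector("list", length(usable))
    for (j in seq_along(usable)) {
      i <- usable[j]
      n <- lens[i] - k + 1L
      parts[[j]] <- data.table::data.table(
        kmer = substring(sequences[i], 1:n, k:lens[i]),
        tid = i, pos = 1:n
      )
    }
    tab <- data.table::rbindlist(parts)
  }
  data.table::setkey(tab, kmer)
  structure(list(table = tab, sequences = sequences,
                 lengths = lens, ids = names(sequences), k = k),
            class = "ribote_index")
}

#' Align reads to an indexed transcript set (exact match, multi-map cap)
#'
#' Finds all exact full-length occurrences of each read. A read with between
#' 1 and `max_multimap` occurrences yields one hit per occurrence; a read
#' with more occurrences than the cap is suppressed entirely (no hits
#' reported), mirroring an aligner invoked with `-v 0 -m 25`. Reads shorter
#' than the index seed length are skipped and counted.
#'
#' @param reads data frame with `read_id` and `sequence` columns (or a named
#'   character vector of sequences).
#' @param index a `ribote_index` from [build_index()].
#' @param max_multimap suppress reads with more than this many occurrences
#'   (default 25).
#' @param mismatches_allowed must be 0; mismatch-tolerant alignment is
#'   reserved and unimplemented.
#' @param reverse_complement also search the reverse complement of each read
#'   (off by default: footprints of mRNA are sense-strand).
#' @return list with `hits` (data frame: read_id, transcript_id, start
#'   0-based, length) and `summary` (named counts: n_reads, n_short,
#'   n_unaligned, n_suppressed, n_aligned_reads, n_hits).
#' @export
align_reads <- function(reads, index, max_multimap = 25L,
                        mismatches_allowed = 0L, reverse_complement = FALSE) {
  stopifnot(inherits(index, "ribote_index"))
  if (mismatches_allowed != 0L) {
    stop("mismatches_allowed must be 0 (mismatch-tolerant mode is reserved)")
  }
  if (is.character(reads)) {
    reads <- data.frame(read_id = if (is.null(names(reads)))
      sprintf("read_%06d", seq_along(reads)) else names(reads),
      sequence = unname(reads), stringsAsFactors = FALSE)
  }
  n_reads <- nrow(reads)
  len <- nchar(reads$sequence)
  short <- len < index$k
  n_short <- sum(short)

  empty_hits <- data.frame(read_id = character(0), transcript_id = character(0),
                           start = integer(0), length = integer(0),
                           stringsAsFactors = FALSE)
  keep <- which(!short)
  match_pass <- function(seqs) {
    if (length(keep) == 0L || nrow(index$table) == 0L) {
      return(data.frame(rid = integer(0), tid = integer(0), pos = integer(0)))
    }
    q <- data.table::data.table(kmer = substr(seqs[keep], 1L, index$k),
                                rid = keep)
    m <- index$table[q, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
    if (nrow(m) == 0L) {
      return(data.frame(rid = integer(0), tid = integer(0), pos = integer(0)))
    }
    rl <- len[m$rid]
    fits <- m$pos + rl - 1L <= index$lengths[m$tid]
    m <- m[fits]
    rl <- len[m$rid]
    ok <- substr(index$sequences[m$tid], m$pos, m$pos + rl - 1L) == seqs[m$rid]
    as.data.frame(m[ok, c("rid", "tid", "pos")])
  }

  hits <- match_pass(reads$sequence)
  if (isTRUE(reverse_complement)) {
    rc <- character(n_reads)
    rc[keep] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads$sequence[keep])))
    hits <- unique(rbind(hits, match_pass(rc)))
  }

  n_occ <- tabulate(hits$rid, nbins = n_reads)
  suppressed <- n_occ > max_multimap
  retained <- hits[!suppressed[hits$rid], , drop = FALSE]

  out <- if (nrow(retained) == 0L) empty_hits else data.frame(
    read_id = reads$read_id[retained$rid],
    transcript_id = index$ids[retained$tid],
    start = retained$pos - 1L,
    length = len[retained$rid],
    stringsAsFactors = FALSE
  )
  summary <- c(n_reads = n_reads, n_short = n_short,
               n_unaligned = sum(n_occ == 0L & !short),
               n_suppressed = sum(suppressed),
               n_aligned_reads = sum(n_occ >= 1L & !suppressed),
               n_hits = nrow(out))
  list(hits = out, summary = summary)
}

#' Remove rDNA-flagged models and their hits
#'
#' Reads matching rDNA-contaminated models are excluded from all further
#' analysis, including the per-library mapped-read totals used for
#' normalization.
#'
#' @param models transcript model data frame with an `is_rdna` column.
#' @param hits hit data frame (or a list of them, one per library).
#' @return list with `models` (retained), `hits` (same shape as input,
#'   rDNA hits dropped), `removed_models` and `removed_hits` counts.
#' @export
exclude_rdna <- function(models, hits) {
  rdna_ids <- models$transcript_id[models$is_rdna]
  drop_one <- function(h) h[!(h$transcript_id %in% rdna_ids), , drop = FALSE]
  if (is.data.frame(hits)) {
    removed <- sum(hits$transcript_id %in% rdna_ids)
    hits <- drop_one(hits)
  } else {
    removed <- sum(vapply(hits, function(h) sum(h$transcript_id %in% rdna_ids), 0))
    hits <- lapply(hits, drop_one)
  }
  list(models = models[!models$is_rdna, , drop = FALSE],
       hits = hits,
       removed_models = length(rdna_ids),
       removed_hits = removed)
}

.parse_library_key <- function(key) {
  m <- regmatches(key, regexec("^(.*?)(CT|FP)_rep([0-9]+)$", key))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) stop("unparsable library key(s): ", paste(key[bad], collapse = ", "))
  data.frame(library = key,
             stage = vapply(m, `[`, "", 2L),
             type = vapply(m, `[`, "", 3L),
             replicate = as.integer(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

#' Count hits per transcript per library
#'
#' Builds the raw count matrix: cell (t, lib) is the number of alignments to
#' transcript t in that library. A multi-mapped read contributes one count to
#' every transcript position it matched. `total_mapped` is the column sum
#' over the retained transcripts.
#'
#' @param hit_list named list of hit data frames, keyed
#'   `<stage><type>_rep<i>` (e.g. `C25FP_rep1`).
#' @param models retained transcript model data frame (rDNA already
#'   excluded).
#' @return object of class `count_matrix`: list with `counts` (integer
#'   matrix, transcripts x libraries), `libraries` (stage/type/replicate
#'   table) and `total_mapped`.
#' @export
count_hits <- function(hit_list, models) {
  libs <- .parse_library_key(names(hit_list))
  counts <- matrix(0L, nrow(models), nrow(libs),
                   dimnames = list(models$transcript_id, libs$library))
  for (j in seq_along(hit_list)) {
    h <- hit_list[[j]]
    if (nrow(h) == 0L) next
    idx <- match(h$transcript_id, models$transcript_id)
    if (anyNA(idx)) {
      stop("hit to unknown transcript: ",
           h$transcript_id[which(is.na(idx))[1]])
    }
    tb <- tabulate(idx, nbins = nrow(models))
    counts[, j] <- tb
  }
  structure(list(counts = counts, libraries = libs,
                 total_mapped = colSums(counts)),
            class = "count_matrix")
}
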