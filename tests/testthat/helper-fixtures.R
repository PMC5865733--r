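# small simulation used across unit tests
tiny_config <- function(seed = 7L, ...) {
  defaults <- list(
    n_genes = 40L, reads_per_library = 8000L,
    n_organelle_genes = c(chloroplast = 3L, mitochondrion = 2L),
    organelle_copy_identities = c(1.0, 0.85),
    n_paralog_pairs = 1L, n_rdna_models = 2L, seed = seed)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# literal brute-force exact substring search with the same suppression
# rule as the aligner; checks every start offset, overlapping matches
# included
brute_force_hits <- function(reads, seqs, max_multimap = 25L, min_len = 20L) {
  rows <- list()
  for (i in seq_len(nrow(reads))) {
    s <- reads$sequence[i]
    n <- nchar(s)
    if (n < min_len) next
    occ <- list()
    for (tx in names(seqs)) {
      L <- nchar(seqs[[tx]])
      if (L < n) next
      starts <- seq_len(L - n + 1L)
      hitpos <- starts[substring(seqs[[tx]], starts, starts + n - 1L) == s]
      for (p in hitpos) {
        occ[[length(occ) + 1L]] <- data.frame(
          read_id = reads$read_id[i], transcript_id = tx,
          start = p - 1L, length = n, stringsAsFactors = FALSE)
      }
    }
    if (length(occ) >= 1L && length(occ) <= max_multimap) {
      rows <- c(rows, occ)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(read_id = character(0), transcript_id = character(0),
                      start = integer(0), length = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

sort_hits <- function(h) {
  h <- h[order(h$read_id, h$transcript_id, h$start), , drop = FALSE]
  rownames(h) <- NULL
  h
}

extdata <- function(f) {
  read.delim(system.file("extdata", f, package = "riboTE"),
             stringsAsFactors = FALSE)
}
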