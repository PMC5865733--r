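#' Write transcript models as GFF3
#'
#' Emits gene / mRNA / five_prime_UTR / CDS / three_prime_UTR features in
#' transcript coordinates (1-based inclusive, seqid = transcript id).
#' Zero-length UTRs are omitted.
#'
#' @param models transcript model data frame (see [build_transcriptome()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_models_gff3 <- function(models, path) {
  rows <- list()
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    feat <- function(type, start0, end0, id, parent = NA) {
      if (end0 <= start0) return(NULL)
      GenomicRanges::GRanges(
        seqnames = m$transcript_id,
        ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
        strand = "+", type = type, ID = id,
        phase = if (type == "CDS") 0L else NA_integer_,
        Parent = IRanges::CharacterList(
          if (is.na(parent)) character(0) else parent)
      )
    }
    rows[[length(rows) + 1L]] <- feat("gene", 0L, m$length, m$gene_id)
    rows[[length(rows) + 1L]] <- feat("mRNA", 0L, m$length, m$transcript_id, m$gene_id)
    rows[[length(rows) + 1L]] <- feat("five_prime_UTR", 0L, m$cds_start,
                                      paste0(m$transcript_id, ".utr5"), m$transcript_id)
    rows[[length(rows) + 1L]] <- feat("CDS", m$cds_start, m$cds_end,
                                      paste0(m$transcript_id, ".cds"), m$transcript_id)
    rows[[length(rows) + 1L]] <- feat("three_prime_UTR", m$cds_end, m$length,
                                      paste0(m$transcript_id, ".utr3"), m$transcript_id)
  }
  gr <- suppressWarnings(do.call(c, rows[!vapply(rows, is.null, TRUE)]))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read transcript models back from GFF3
#'
#' Inverse of [write_models_gff3()]: parses mRNA and CDS features (transcript
#' coordinates) into the internal 0-based half-open model table. rDNA models
#' are recognized by their `rDNA.` identifier prefix.
#'
#' @param path GFF3 file.
#' @return transcript model data frame.
#' @export
read_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mrna <- gr[gr$type == "mRNA"]
  cds <- gr[gr$type == "CDS"]
  tid <- as.character(mrna$ID)
  cds_of <- match(tid, as.character(GenomicRanges::seqnames(cds)))
  data.frame(
    transcript_id = tid,
    gene_id = as.character(unlist(mrna$Parent)),
    length = GenomicRanges::end(mrna),
    cds_start = GenomicRanges::start(cds)[cds_of] - 1L,
    cds_end = GenomicRanges::end(cds)[cds_of],
    is_rdna = startsWith(tid, "rDNA."),
    stringsAsFactors = FALSE
  )
}

#' Write reads as FASTQ
#'
#' Four-line records with a constant placeholder quality (Sanger offset-33
#' "I"); the simulator does not model quality scores.
#'
#' @param reads read data frame with `read_id` and `sequence` columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads$sequence)
  names(dna) <- reads$read_id
  qual <- Biostrings::PhredQuality(strrep("I", Biostrings::width(dna)))
  qdna <- Biostrings::QualityScaledDNAStringSet(dna, qual)
  Biostrings::writeQualityScaledXStringSet(qdna, path)
  invisible(path)
}

#' Read a FASTQ file into a read data frame
#'
#' @param path FASTQ file.
#' @return data frame with read_id and sequence columns.
#' @export
read_reads_fastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = names(dna), sequence = as.character(dna),
             stringsAsFactors = FALSE, row.names = NULL)
}

.write_fasta <- function(seqs, path) {
  dna <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

.read_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(dna), names(dna))
}

#' Write a complete simulated fixture to disk
#'
#' Writes the transcript FASTA, GFF3 annotation, per-organelle genome FASTA
#' and CDS GFF3, one FASTQ per simulated library, the ground-truth table
#' (TSV), and a manifest of MD5 checksums.
#'
#' @param sim a `ribote_sim` from [build_transcriptome()].
#' @param dir output directory (created if absent).
#' @param libraries optional pre-simulated list from
#'   [simulate_all_libraries()]; simulated on the fly when NULL.
#' @return manifest data frame (file, md5), invisibly.
#' @export
write_fixture <- function(sim, dir, libraries = NULL) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create fixture directory: ", dir)
  }
  files <- character(0)
  p <- function(f) file.path(dir, f)

  .write_fasta(sim$sequences, p("transcriptome.fasta"))
  files <- c(files, "transcriptome.fasta")
  write_models_gff3(sim$models, p("annotation.gff3"))
  files <- c(files, "annotation.gff3")

  for (org in names(sim$organelles)) {
    o <- sim$organelles[[org]]
    fa <- sprintf("organelle_%s.fasta", org)
    .write_fasta(stats::setNames(o$genome, org), p(fa))
    gr <- GenomicRanges::GRanges(
      seqnames = org,
      ranges = IRanges::IRanges(start = o$cds$start, end = o$cds$end),
      strand = o$cds$strand, type = "CDS", ID = o$cds$cds_id,
      phase = 0L
    )
    gf <- sprintf("organelle_%s.gff3", org)
    rtracklayer::export(gr, p(gf), format = "gff3")
    files <- c(files, fa, gf)
  }

  if (is.null(libraries)) libraries <- simulate_all_libraries(sim)
  for (key in names(libraries)) {
    fq <- sprintf("%s.fastq", key)
    write_reads_fastq(libraries[[key]], p(fq))
    files <- c(files, fq)
  }

  utils::write.table(sim$truth, p("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, "truth.tsv")

  md5 <- tools::md5sum(file.path(dir, files))
  manifest <- data.frame(file = files, md5 = unname(md5),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
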