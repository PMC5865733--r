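#' RPKM normalization of a count matrix
#'
#' Reads per kilobase of model per million mapped reads:
#' `rpkm = count * 1e9 / (length_nt * total_mapped)`.
#'
#' @param counts a `count_matrix` from [count_hits()].
#' @param lengths named numeric vector of transcript lengths (nt), covering
#'   every row of the matrix.
#' @return numeric matrix of RPKM values with the same dimnames.
#' @export
rpkm <- function(counts, lengths) {
  stopifnot(inherits(counts, "count_matrix"))
  L <- lengths[rownames(counts$counts)]
  if (anyNA(L)) stop("missing length for transcript(s): ",
                     rownames(counts$counts)[which(is.na(L))[1]])
  if (any(L <= 0)) stop("transcript lengths must be positive")
  tm <- counts$total_mapped
  if (any(tm == 0)) {
    stop("zero mapped reads in library: ",
         names(tm)[which(tm == 0)[1]])
  }
  sweep(counts$counts * 1e9 / L, 2L, tm, "/")
}

#' Average replicate RPKMs within each (stage, type), with optional floor
#'
#' Replicate averaging is of RPKM values (not raw counts). With
#' `apply_floor`, averaged values below `floor_value` are raised to it; the
#' floor guarantees a defined TE ratio (and makes TE exactly 1 when both
#' members of a pair sit at the floor).
#'
#' @param rpkm_matrix RPKM matrix from [rpkm()] (columns are libraries).
#' @param libraries library table (`counts$libraries`) describing the
#'   columns.
#' @param floor_value reporting floor (default 0.1 RPKM).
#' @param apply_floor apply the floor (default TRUE).
#' @return list with `rep_avg` (matrix, transcripts x `<stage>_<type>`
#'   columns), `stages`, `floor_value`, `floor_applied`.
#' @export
average_replicates <- function(rpkm_matrix, libraries, floor_value = 0.1,
                               apply_floor = TRUE) {
  key <- paste(libraries$stage, libraries$type, sep = "_")
  groups <- unique(key)
  stages <- unique(libraries$stage)
  for (s in stages) for (ty in c("CT", "FP")) {
    if (!paste(s, ty, sep = "_") %in% groups) {
      stop("missing library group: stage ", s, " type ", ty)
    }
  }
  avg <- vapply(groups, function(g) {
    rowMeans(rpkm_matrix[, key == g, drop = FALSE])
  }, numeric(nrow(rpkm_matrix)))
  if (is.null(dim(avg))) avg <- matrix(avg, nrow = 1,
                                       dimnames = list(rownames(rpkm_matrix), groups))
  if (apply_floor) avg <- pmax(avg, floor_value)
  list(rep_avg = avg, stages = stages,
       floor_value = floor_value, floor_applied = apply_floor)
}

#' Assign an aligned read to a transcript region
#'
#' Returns the region (5'UTR, CDS, 3'UTR) containing the majority of the
#' read's bases; an exact tie goes to the 5'-most tied region. With
#' `rule = "five_prime_end"` the region containing the read's first base is
#' used instead.
#'
#' @param start 0-based read start(s) on the transcript.
#' @param length read length(s) (> 0).
#' @param model one transcript model row (with `cds_start`, `cds_end`,
#'   `length`), or vectors via `cds_start`/`cds_end`/`tx_length`.
#' @param cds_start,cds_end,tx_length per-read model coordinates
#'   (0-based half-open CDS) used when `model` is NULL.
#' @param rule assignment rule (default base-majority).
#' @return character vector over `c("utr5", "cds", "utr3")`.
#' @export
assign_region <- function(start, length, model = NULL,
                          cds_start = NULL, cds_end = NULL, tx_length = NULL,
                          rule = c("majority", "five_prime_end")) {
  rule <- match.arg(rule)
  if (!is.null(model)) {
    cds_start <- model$cds_start; cds_end <- model$cds_end
    tx_length <- model$length
  }
  if (any(length <= 0)) stop("zero-length read")
  end <- start + length            # half-open [start, end)
  if (any(start < 0) || any(end > tx_length)) stop("read not on transcript")
  if (rule == "five_prime_end") {
    out <- ifelse(start < cds_start, "utr5",
                  ifelse(start < cds_end, "cds", "utr3"))
    return(out)
  }
  ov <- function(lo, hi) pmax(0L, pmin(end, hi) - pmax(start, lo))
  b5 <- ov(0L, cds_start)
  bc <- ov(cds_start, cds_end)
  b3 <- ov(cds_end, tx_length)
  # 5'-most tied region wins: compare in 5' -> 3' order with >=
  out <- ifelse(b5 >= bc & b5 >= b3, "utr5", ifelse(bc >= b3, "cds", "utr3"))
  out
}

#' Per-region hit counts for each transcript in each library
#'
#' @param hit_list named list of hit data frames (post rDNA exclusion).
#' @param models retained transcript models.
#' @param rule region assignment rule, see [assign_region()].
#' @return data frame: library, transcript_id, utr5, cds, utr3 counts.
#' @export
region_counts <- function(hit_list, models, rule = "majority") {
  out <- list()
  for (lib in names(hit_list)) {
    h <- hit_list[[lib]]
    if (nrow(h) == 0L) next
    mi <- match(h$transcript_id, models$transcript_id)
    reg <- assign_region(h$start, h$length,
                         cds_start = models$cds_start[mi],
                         cds_end = models$cds_end[mi],
                         tx_length = models$length[mi],
                         rule = rule)
    tab <- table(factor(h$transcript_id, levels = models$transcript_id),
                 factor(reg, levels = c("utr5", "cds", "utr3")))
    df <- as.data.frame.matrix(tab)
    df <- data.frame(library = lib, transcript_id = rownames(df), df,
                     stringsAsFactors = FALSE, row.names = NULL)
    out[[lib]] <- df
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' CDS-normalized footprint-to-control region ratios
#'
#' For each region, computes `(FP_region / CT_region) / (FP_cds / CT_cds)`,
#' so that the CDS ratio is 1.00 by construction and UTR values express
#' footprint depletion relative to the CDS. A region with zero footprint
#' reads reports 0.00; a region with control count zero but footprint reads
#' present is flagged undefined (NA); a zero CDS count in either library
#' makes the whole row not computable.
#'
#' @param ct_counts,fp_counts numeric vectors or single-row data frames with
#'   entries `utr5`, `cds`, `utr3` of raw region read counts.
#' @return data frame with utr5_ratio, cds_ratio, utr3_ratio (rounded
#'   half-away-from-zero to 2 decimals), full-precision companions, and a
#'   `computable` flag.
#' @export
region_ratio_table <- function(ct_counts, fp_counts) {
  ct <- unlist(ct_counts[c("utr5", "cds", "utr3")])
  fp <- unlist(fp_counts[c("utr5", "cds", "utr3")])
  if (ct[["cds"]] == 0 || fp[["cds"]] == 0) {
    return(data.frame(utr5_ratio = NA_real_, cds_ratio = NA_real_,
                      utr3_ratio = NA_real_, utr5_ratio_full = NA_real_,
                      cds_ratio_full = NA_real_, utr3_ratio_full = NA_real_,
                      computable = FALSE))
  }
  cds_rr <- fp[["cds"]] / ct[["cds"]]
  one <- function(region) {
    if (fp[[region]] == 0) return(0)
    if (ct[[region]] == 0) return(NA_real_)
    (fp[[region]] / ct[[region]]) / cds_rr
  }
  full <- c(utr5 = one("utr5"), cds = 1, utr3 = one("utr3"))
  data.frame(utr5_ratio = round_half_up(full[["utr5"]]),
             cds_ratio = 1.00,
             utr3_ratio = round_half_up(full[["utr3"]]),
             utr5_ratio_full = full[["utr5"]],
             cds_ratio_full = 1,
             utr3_ratio_full = full[["utr3"]],
             computable = TRUE)
}
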