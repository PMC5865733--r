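#' Translational efficiency from replicate-averaged RPKMs
#'
#' TE is the normalized footprint abundance divided by the normalized mRNA
#' abundance: `te = fp_rpkm / ct_rpkm`. Reported values are rounded
#' half-away-from-zero to two decimals; the full-precision ratio is kept
#' internally.
#'
#' @param ct_rpkm,fp_rpkm replicate-averaged (post-floor) RPKM vectors.
#' @return data frame with `te` (full precision) and `te_round`.
#' @export
#' @examples
#' compute_te(377, 498)$te_round   # 1.32
compute_te <- function(ct_rpkm, fp_rpkm) {
  te <- ifelse(ct_rpkm > 0, fp_rpkm / ct_rpkm, NA_real_)
  if (anyNA(te)) {
    warning(sum(is.na(te)), " transcript(s) with CT RPKM 0 and floor disabled; TE undefined")
  }
  data.frame(te = te, te_round = round_half_up(te))
}

#' Replace zero counts by one for count-based testing
#'
#' The negative-binomial test operates on raw hit counts; zero cells are
#' converted to 1 so that no transcript is lost from the dispersion and
#' size-factor machinery. The conversion applies only to the test's inputs,
#' never to RPKM values (which use the reporting floor instead).
#'
#' @param counts a `count_matrix` or plain integer matrix.
#' @param stage optional stage label; when given, only that stage's CT and
#'   FP columns are returned.
#' @return same shape as the input with every 0 replaced by 1; for a
#'   `count_matrix` input a list (counts, libraries) restricted to the stage.
#' @export
prepare_test_counts <- function(counts, stage = NULL) {
  if (inherits(counts, "count_matrix")) {
    keep <- if (is.null(stage)) seq_len(ncol(counts$counts)) else
      which(counts$libraries$stage == stage)
    if (length(keep) == 0L) stop("stage not present: ", stage)
    libs <- counts$libraries[keep, , drop = FALSE]
    if (!all(c("CT", "FP") %in% libs$type)) {
      stop("need at least one CT and one FP library for stage ", stage)
    }
    m <- counts$counts[, keep, drop = FALSE]
    m[m == 0L] <- 1L
    return(list(counts = m, libraries = libs))
  }
  counts[counts == 0] <- 1L
  counts
}

#' Median-of-ratios size factors
#'
#' The per-library scaling constant of the count-based test: for each
#' library, the median over transcripts (with all-positive counts) of the
#' ratio of its count to the per-transcript geometric mean across libraries.
#'
#' @param counts integer matrix, transcripts x libraries (zeros already
#'   converted if desired).
#' @return positive numeric vector, one factor per column.
#' @export
size_factors <- function(counts) {
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use)) {
    stop("no transcript with all-positive counts; convert zeros to 1 first")
  }
  apply(counts, 2L, function(col) {
    exp(stats::median(log(col[use]) - log_gm[use]))
  })
}

# method-of-moments dispersion pooled across the two conditions,
# optionally shrunk toward a local-regression mean-dispersion trend
.dispersions <- function(counts, sf, condition, min_disp = 1e-8,
                         trend_min_n = 100L, prior_df = 10) {
  z <- sweep(counts, 2L, sf, "/")
  q <- rowMeans(z)
  conds <- unique(condition)
  sse <- numeric(nrow(counts))
  for (cc in conds) {
    zc <- z[, condition == cc, drop = FALSE]
    sse <- sse + rowSums((zc - rowMeans(zc))^2)
  }
  df <- ncol(counts) - length(conds)
  if (df <= 0) return(rep(min_disp, nrow(counts)))
  varz <- sse / df
  xim <- mean(1 / sf)
  raw <- (varz - q * xim) / q^2
  raw[!is.finite(raw)] <- 0
  if (nrow(counts) >= trend_min_n) {
    use <- is.finite(raw) & q > 0
    if (sum(use) >= 20L) {
      # trend fitted on the raw (mean-unbiased) scale: the method-of-moments
      # estimate is unbiased for the dispersion but very noisy at 2 residual
      # df, so individual estimates (negative values included) are shrunk
      # toward the fitted mean-dispersion trend
      dd <- data.frame(x = log(q[use]), y = raw[use])
      fit <- stats::loess(y ~ x, data = dd, span = 0.6,
                          control = stats::loess.control(surface = "direct"))
      qc <- log(pmax(q, min(q[q > 0])))
      trend <- stats::predict(fit, newdata = data.frame(x = qc))
      trend[!is.finite(trend)] <- stats::median(raw[use])
      disp <- (prior_df * trend + df * raw) / (prior_df + df)
    } else {
      disp <- pmax(raw, 0)
    }
  } else {
    disp <- pmax(raw, 0)
  }
  pmax(disp, min_disp)
}

#' Negative-binomial exact test for footprint vs control counts
#'
#' Per-transcript two-sided p-values comparing the CT and FP conditions of
#' one stage, using the classic negative-binomial exact test: counts are
#' normalized by median-of-ratios size factors; a per-transcript dispersion
#' is estimated by method of moments pooled across both conditions (shrunk
#' toward a local-regression mean-dispersion trend when at least 100
#' transcripts are available, and floored at 1e-8); the p-value is the
#' probability, under a negative-binomial model with a common mean, of
#' CT/FP count splits at least as improbable as the observed one,
#' conditioned on the total.
#'
#' @param ct_counts,fp_counts integer matrices (transcripts x replicates)
#'   with zeros already converted to 1 (see [prepare_test_counts()]).
#' @param sf optional size factors for `cbind(ct_counts, fp_counts)`;
#'   estimated when NULL.
#' @param dispersions optional per-transcript dispersions; estimated when
#'   NULL.
#' @return numeric vector of p-values in (0, 1].
#' @export
nb_test <- function(ct_counts, fp_counts, sf = NULL, dispersions = NULL) {
  ct_counts <- as.matrix(ct_counts); fp_counts <- as.matrix(fp_counts)
  if (any(ct_counts != round(ct_counts)) || any(fp_counts != round(fp_counts))) {
    stop("counts must be integers")
  }
  k <- cbind(ct_counts, fp_counts)
  condition <- rep(c("CT", "FP"), c(ncol(ct_counts), ncol(fp_counts)))
  if (is.null(sf)) sf <- size_factors(k)
  if (is.null(dispersions)) dispersions <- .dispersions(k, sf, condition)

  sA <- sum(sf[condition == "CT"]); sB <- sum(sf[condition == "FP"])
  s2A <- sum(sf[condition == "CT"]^2); s2B <- sum(sf[condition == "FP"]^2)
  z <- sweep(k, 2L, sf, "/")
  q <- rowMeans(z)

  kA <- rowSums(ct_counts); kB <- rowSums(fp_counts)
  n <- nrow(k)
  pval <- numeric(n)
  for (i in seq_len(n)) {
    kS <- kA[i] + kB[i]
    muA <- q[i] * sA; muB <- q[i] * sB
    vA <- muA + dispersions[i] * q[i]^2 * s2A
    vB <- muB + dispersions[i] * q[i]^2 * s2B
    szA <- if (vA > muA) muA^2 / (vA - muA) else 1e12
    szB <- if (vB > muB) muB^2 / (vB - muB) else 1e12
    a <- 0:kS
    # conditional split distribution computed in log space: only relative
    # probabilities across splits matter, and the joint NB mass underflows
    # for strongly asymmetric libraries
    lp <- stats::dnbinom(a, size = szA, mu = muA, log = TRUE) +
      stats::dnbinom(kS - a, size = szB, mu = muB, log = TRUE)
    lmax <- max(lp[is.finite(lp)])
    if (!is.finite(lmax)) { pval[i] <- 1; next }
    w <- exp(lp - lmax)
    lp_obs <- lp[kA[i] + 1L]
    pval[i] <- min(1, sum(w[lp <= lp_obs + 1e-7]) / sum(w))
  }
  pval[pval <= 0] <- .Machine$double.xmin
  pval
}

#' Assemble the master TE result table for all stages
#'
#' Joins replicate-averaged RPKMs, TE ratios and per-stage negative-binomial
#' p-values into one row per transcript per stage, plus an informational
#' Benjamini-Hochberg column (the filters use the raw p-value).
#'
#' @param counts a `count_matrix` (rDNA already excluded).
#' @param lengths named transcript length vector.
#' @param floor_value RPKM reporting floor (default 0.1).
#' @param apply_floor apply the floor before TE computation (default TRUE).
#' @return data frame: transcript_id, gene_id, stage, ct_rpkm, fp_rpkm, te,
#'   te_round, pvalue, padj.
#' @export
te_table <- function(counts, lengths, floor_value = 0.1, apply_floor = TRUE) {
  r <- rpkm(counts, lengths)
  avg <- average_replicates(r, counts$libraries, floor_value, apply_floor)
  out <- list()
  for (stage in avg$stages) {
    tc <- prepare_test_counts(counts, stage)
    ct <- tc$counts[, tc$libraries$type == "CT", drop = FALSE]
    fp <- tc$counts[, tc$libraries$type == "FP", drop = FALSE]
    p <- nb_test(ct, fp)
    ctr <- avg$rep_avg[, paste(stage, "CT", sep = "_")]
    fpr <- avg$rep_avg[, paste(stage, "FP", sep = "_")]
    te <- compute_te(ctr, fpr)
    out[[stage]] <- data.frame(
      transcript_id = rownames(counts$counts),
      gene_id = gene_id_of(rownames(counts$counts), warn = FALSE),
      stage = stage,
      ct_rpkm = unname(ctr), fp_rpkm = unname(fpr),
      te = te$te, te_round = te$te_round,
      pvalue = p, padj = stats::p.adjust(p, "BH"),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "floor_value") <- floor_value
  attr(res, "floor_applied") <- apply_floor
  res
}

#' Filtering criteria for high- or low-TE transcript selection
#'
#' @param pval_max retain transcripts with `pvalue < pval_max` (strict).
#' @param te_bound TE threshold.
#' @param te_direction `"greater"` retains `te > te_bound` (strict, the
#'   high-TE rule); `"at_most"` retains `te <= te_bound` (inclusive, the
#'   low-TE rule).
#' @param abundance_field `"fp_rpkm"` or `"ct_rpkm"`.
#' @param abundance_min retain `abundance >= abundance_min` (inclusive).
#' @return a `filter_criteria` object.
#' @export
filter_criteria <- function(pval_max = 0.05, te_bound = 1,
                            te_direction = c("greater", "at_most"),
                            abundance_field = c("fp_rpkm", "ct_rpkm"),
                            abundance_min = 1) {
  te_direction <- match.arg(te_direction)
  abundance_field <- match.arg(abundance_field)
  stopifnot(pval_max > 0, te_bound > 0, abundance_min > 0)
  structure(list(pval_max = pval_max, te_bound = te_bound,
                 te_direction = te_direction,
                 abundance_field = abundance_field,
                 abundance_min = abundance_min),
            class = "filter_criteria")
}

#' The high-TE selection rule: Pval < 0.05, TE > 1, FP RPKM >= 1
#' @return a `filter_criteria` object.
#' @export
high_te_criteria <- function() {
  filter_criteria(0.05, 1, "greater", "fp_rpkm", 1)
}

#' The low-TE selection rule: Pval < 0.05, TE <= 0.1, CT RPKM >= 10
#' @return a `filter_criteria` object.
#' @export
low_te_criteria <- function() {
  filter_criteria(0.05, 0.1, "at_most", "ct_rpkm", 10)
}

#' Filter one stage of TE results by a criteria set
#'
#' Exact conjunction of the three thresholds, with the strict/inclusive
#' comparisons of the published rules: p-value strictly below `pval_max`; TE
#' strictly above the bound for high-TE (or at-most the bound, inclusive,
#' for low-TE); abundance at least `abundance_min` (inclusive). Rows with a
#' missing p-value are excluded and counted in a warning.
#'
#' @param te_results table from [te_table()].
#' @param criteria a [filter_criteria()].
#' @param stage stage label to filter.
#' @param exclude optional transcript ids to drop before filtering (e.g. a
#'   user-supplied list of models with aberrant RPKMs).
#' @return character vector of passing transcript ids.
#' @export
filter_transcripts <- function(te_results, criteria, stage, exclude = NULL) {
  stopifnot(inherits(criteria, "filter_criteria"))
  d <- te_results[te_results$stage == stage, , drop = FALSE]
  if (nrow(d) == 0L) stop("no results for stage ", stage)
  if (!is.null(exclude)) d <- d[!(d$transcript_id %in% exclude), , drop = FALSE]
  miss <- is.na(d$pvalue)
  if (any(miss)) {
    warning(sum(miss), " transcript(s) without a p-value excluded")
    d <- d[!miss, , drop = FALSE]
  }
  te_ok <- if (criteria$te_direction == "greater") d$te > criteria$te_bound
  else d$te <= criteria$te_bound
  pass <- d$pvalue < criteria$pval_max & te_ok &
    d[[criteria$abundance_field]] >= criteria$abundance_min
  d$transcript_id[pass]
}

#' Collapse transcript sets to unique genes across stages
#'
#' Strips the terminal splice-variant suffix from each passing transcript id
#' and reports per-stage transcript/primary counts plus the cross-stage
#' union of unique genes.
#'
#' @param stage_sets named list (stage -> character vector of transcript
#'   ids).
#' @return list of class `gene_set`: `per_stage` (data frame with stage,
#'   n_transcripts, n_primary (distinct genes within the stage)), `genes`
#'   (per-stage gene id lists), `union_genes`, `n_union`.
#' @export
collapse_unique_genes <- function(stage_sets) {
  genes <- lapply(stage_sets, gene_id_of)
  per_stage <- data.frame(
    stage = names(stage_sets),
    n_transcripts = vapply(stage_sets, length, 0L),
    n_primary = vapply(genes, function(g) length(unique(g)), 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  union_genes <- unique(unlist(genes, use.names = FALSE))
  structure(list(per_stage = per_stage, genes = lapply(genes, unique),
                 union_genes = union_genes,
                 n_union = length(union_genes)),
            class = "gene_set")
}

#' Expressed-transcript counts and percentages
#'
#' Counts transcripts (and unique genes) whose replicate-averaged control
#' RPKM meets the expression cut-off, per stage.
#'
#' @param te_results table from [te_table()].
#' @param threshold expression cut-off (default 1 RPKM, inclusive).
#' @return data frame: stage, n_transcripts, n_genes.
#' @export
expressed_counts <- function(te_results, threshold = 1) {
  stages <- unique(te_results$stage)
  out <- lapply(stages, function(s) {
    d <- te_results[te_results$stage == s & te_results$ct_rpkm >= threshold, ]
    data.frame(stage = s, n_transcripts = nrow(d),
               n_genes = length(unique(d$gene_id)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Percentage of a gene set relative to an expressed denominator
#'
#' @param n_set size of the gene set (e.g. unique high-TE genes at a stage).
#' @param n_expressed expressed-gene denominator at the same stage.
#' @param digits decimal places (default 2).
#' @return percentage rounded half-away-from-zero.
#' @export
#' @examples
#' percent_of_expressed(136, 14888)  # 0.91
percent_of_expressed <- function(n_set, n_expressed, digits = 2) {
  round_half_up(100 * n_set / n_expressed, digits)
}
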