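#' Pearson correlation distance between two profiles
#'
#' `d = 1 - r`, where r is the Pearson correlation coefficient; ranges over
#' \[0, 2\]. Undefined for profiles with zero variance (callers must
#' pre-filter such rows).
#'
#' @param x,y numeric profiles of equal length >= 2.
#' @return distance in \[0, 2\].
#' @export
#' @examples
#' pearson_distance(c(1, 2, 3), c(3, 2, 1))  # 2
pearson_distance <- function(x, y) {
  if (length(x) < 2L || length(x) != length(y)) {
    stop("profiles must have equal length >= 2")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Pearson distance undefined for a zero-variance profile")
  }
  1 - stats::cor(x, y)
}

# row-wise z-standardization; rows are assumed to have positive variance
.zrows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  (m - mu) / sd
}

#' k-means clustering of TE trajectories under Pearson distance
#'
#' Lloyd-style alternation: profiles are assigned to the nearest centroid by
#' correlation distance (ties broken by the lowest cluster id); each
#' centroid is then recomputed as the mean of its members' z-standardized
#' profiles, re-standardized so the mean remains a valid representative for
#' `1 - r`. An emptied cluster is re-seeded from the point farthest from its
#' centroid. Deterministic for a fixed seed.
#'
#' @param mat numeric matrix, rows = transcripts/genes, ordered stage
#'   columns; zero-variance rows must be removed first (see
#'   [drop_flat_profiles()]).
#' @param k number of clusters (1 <= k <= nrow).
#' @param seed integer seed for the initial centroid draw.
#' @param max_iter iteration cap (default 5e6, the conventional setting of
#'   the clustering tool this mirrors; convergence takes far fewer).
#' @return object of class `cluster_assignment`: labels, centroids
#'   (z-scale), objective (total within-cluster distance), iterations_run,
#'   max_iterations, k, seed.
#' @export
kmeans_cluster <- function(mat, k, seed = 1L, max_iter = 5e6) {
  if (k <= 0) stop("k must be positive")
  if (k > nrow(mat)) stop("k exceeds the number of rows")
  sds <- apply(mat, 1L, stats::sd)
  if (any(sds == 0)) {
    stop(sum(sds == 0), " zero-variance row(s); remove with drop_flat_profiles()")
  }
  z <- .zrows(as.matrix(mat))
  n <- nrow(z); p <- ncol(z)
  set.seed(seed)
  # distinct starting rows (distinct as z-profiles where possible)
  start <- sample.int(n, min(n, max(k * 4L, k)))
  start <- start[!duplicated(round(z[start, , drop = FALSE], 10))]
  if (length(start) < k) start <- sample.int(n, k)
  centroids <- z[start[seq_len(k)], , drop = FALSE]

  dist_to <- function(zm, cen) {
    # 1 - r for z-scored rows: r = (z . c) / (p - 1) when both are z-scored
    1 - (zm %*% t(cen)) / (p - 1)
  }
  labels <- integer(n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d <- dist_to(z, centroids)
    new_labels <- max.col(-d, ties.method = "first")
    for (c_i in seq_len(k)) {
      if (!any(new_labels == c_i)) {       # re-seed an emptied cluster
        far <- which.max(d[cbind(seq_len(n), new_labels)])
        new_labels[far] <- c_i
      }
    }
    for (c_i in seq_len(k)) {
      mem <- z[new_labels == c_i, , drop = FALSE]
      cen <- colMeans(mem)
      if (stats::sd(cen) == 0) cen <- mem[1L, ]    # degenerate mean: keep a member
      centroids[c_i, ] <- (cen - mean(cen)) / stats::sd(cen)
    }
    if (identical(new_labels, labels) || iter >= max_iter) {
      labels <- new_labels
      break
    }
    labels <- new_labels
  }
  d <- dist_to(z, centroids)
  objective <- sum(d[cbind(seq_len(n), labels)])
  structure(list(labels = stats::setNames(labels, rownames(mat)),
                 centroids = centroids, objective = objective,
                 iterations_run = iter, max_iterations = max_iter,
                 k = k, seed = seed),
            class = "cluster_assignment")
}

#' Remove zero-variance (flat) profiles before correlation clustering
#'
#' @param mat profile matrix.
#' @return list with `mat` (rows with positive variance) and `flat` (dropped
#'   row names).
#' @export
drop_flat_profiles <- function(mat) {
  sds <- apply(mat, 1L, stats::sd)
  list(mat = mat[sds > 0, , drop = FALSE],
       flat = rownames(mat)[sds == 0])
}

#' Summarize clusters by annotation family
#'
#' @param assignment a `cluster_assignment`.
#' @param annotation optional data frame (gene_id, family); members without
#'   an entry are counted under "unknown".
#' @return data frame: cluster, n_members, top_family, top_frequency, plus a
#'   `families` list-column of per-cluster frequency tables; centroids are
#'   attached as an attribute.
#' @export
summarize_clusters <- function(assignment, annotation = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  ids <- names(assignment$labels)
  fam <- rep("unknown", length(ids))
  if (!is.null(annotation) && nrow(annotation) > 0) {
    m <- match(gene_id_of(ids, warn = FALSE), annotation$gene_id)
    fam[!is.na(m)] <- annotation$family[m[!is.na(m)]]
  }
  out <- lapply(seq_len(assignment$k), function(c_i) {
    mem <- assignment$labels == c_i
    tab <- sort(table(fam[mem]) / sum(mem), decreasing = TRUE)
    data.frame(cluster = c_i, n_members = sum(mem),
               top_family = names(tab)[1],
               top_frequency = as.numeric(tab[1]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$families <- lapply(seq_len(assignment$k), function(c_i) {
    mem <- assignment$labels == c_i
    table(fam[mem]) / sum(mem)
  })
  attr(res, "centroids") <- assignment$centroids
  res
}

#' Silhouette scan over candidate k
#'
#' Average silhouette width under Pearson correlation distance for each k,
#' reported as guidance for choosing the cluster count (never auto-applied).
#'
#' @param mat profile matrix (no zero-variance rows).
#' @param ks candidate cluster counts (default 2:10).
#' @param seed seed forwarded to [kmeans_cluster()].
#' @return data frame: k, avg_silhouette.
#' @export
silhouette_scan <- function(mat, ks = 2:10, seed = 1L) {
  if (!requireNamespace("cluster", quietly = TRUE)) {
    stop("the 'cluster' package is required for silhouette_scan()")
  }
  z <- .zrows(as.matrix(mat))
  p <- ncol(z)
  dmat <- 1 - (z %*% t(z)) / (p - 1)
  dmat[dmat < 0] <- 0
  ks <- ks[ks < nrow(mat)]
  out <- lapply(ks, function(k) {
    cl <- kmeans_cluster(mat, k, seed = seed)
    sil <- cluster::silhouette(as.integer(cl$labels), dmatrix = dmat)
    data.frame(k = k, avg_silhouette = mean(sil[, "sil_width"]))
  })
  do.call(rbind, out)
}

#' Replicate reproducibility check
#'
#' Pearson correlation between the per-replicate RPKM vectors of each
#' (stage, type) pair, the standard QC that library replicates agree
#' (correlations of roughly 0.8-0.97 indicate reproducible libraries).
#'
#' @param rpkm_matrix RPKM matrix (columns = libraries).
#' @param libraries library table describing the columns.
#' @param log_transform correlate log10(RPKM + 1) values (default TRUE).
#' @return data frame: stage, type, rep_a, rep_b, r.
#' @export
replicate_correlation <- function(rpkm_matrix, libraries, log_transform = TRUE) {
  x <- if (log_transform) log10(rpkm_matrix + 1) else rpkm_matrix
  out <- list()
  for (s in unique(libraries$stage)) for (ty in unique(libraries$type)) {
    cols <- which(libraries$stage == s & libraries$type == ty)
    if (length(cols) < 2L) next
    prs <- utils::combn(cols, 2L)
    for (j in seq_len(ncol(prs))) {
      out[[length(out) + 1L]] <- data.frame(
        stage = s, type = ty,
        rep_a = libraries$replicate[prs[1, j]],
        rep_b = libraries$replicate[prs[2, j]],
        r = stats::cor(x[, prs[1, j]], x[, prs[2, j]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
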