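#' Average-linkage clustering of trajectory frames with a distance cutoff
#'
#' CPPTRAJ-style agglomerative clustering on a pairwise RMSD matrix. Starting
#' from singletons, at each step the pair of clusters with the smallest
#' average pairwise inter-cluster distance (unweighted mean over all cross
#' pairs) is merged; merging stops before the first merge whose linkage
#' distance exceeds `cutoff`, so every pair of final clusters has average
#' distance strictly greater than the cutoff. The number of clusters at the
#' stop is the flexibility metric: flexible loops populate many clusters,
#' rigid loops few.
#'
#' Ties in the minimum linkage distance are broken by the lowest (i, j)
#' cluster-index pair; cluster ids are assigned by decreasing cluster size,
#' ties by lowest member frame.
#'
#' @param mat an [rmsd_matrix()] or a plain symmetric distance matrix.
#' @param cutoff distance cutoff in Angstrom (> 0); 1.2 A is the conventional
#'   loop-clustering choice.
#' @return object of class `"cluster_result"`: list with `labels` (per-frame
#'   cluster id, 1-based), `n_clusters`, `representatives` (per-cluster frame
#'   index), `cutoff`, `linkage = "average"`.
#' @export
average_linkage_cluster <- function(mat, cutoff) {
  d <- if (inherits(mat, "rmsd_matrix")) mat$values else as.matrix(mat)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("need a square distance matrix")
  if (cutoff <= 0) stop("cutoff must be positive")
  f <- nrow(d)
  members <- as.list(seq_len(f))
  size <- rep(1L, f)
  link <- d            # current cluster-cluster average distances
  active <- rep(TRUE, f)
  diag(link) <- Inf
  while (sum(active) > 1L) {
    ai <- which(active)
    sub <- link[ai, ai, drop = FALSE]
    mn <- min(sub)
    if (mn > cutoff) break
    w <- which(sub == mn, arr.ind = TRUE)
    w <- w[w[, 1] < w[, 2], , drop = FALSE]
    w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
    i <- ai[w[1, 1]]; j <- ai[w[1, 2]]
    # UPGMA update: exact cross-pair mean via size weighting
    ni <- size[i]; nj <- size[j]
    newd <- (ni * link[i, ] + nj * link[j, ]) / (ni + nj)
    link[i, ] <- newd; link[, i] <- newd
    link[i, i] <- Inf
    members[[i]] <- c(members[[i]], members[[j]])
    size[i] <- ni + nj
    active[j] <- FALSE
    link[j, ] <- Inf; link[, j] <- Inf
  }
  clusters <- members[active]
  # order clusters by decreasing size, ties by lowest member frame
  low <- vapply(clusters, min, integer(1))
  ord <- order(-lengths(clusters), low)
  clusters <- clusters[ord]
  labels <- integer(f)
  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
  res <- structure(list(labels = labels, n_clusters = length(clusters),
                        representatives = NULL, cutoff = cutoff,
                        linkage = "average"),
                   class = "cluster_result")
  res$representatives <- representatives(d, res)
  res
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Average-linkage clustering: %d frames -> %d clusters (cutoff %.2f A)\n",
              length(x$labels), x$n_clusters, x$cutoff))
  invisible(x)
}

#' Representative frame of each cluster
#'
#' The representative is the member with the smallest average distance to the
#' other members (ties: lowest frame index); a singleton represents itself.
#'
#' @param mat distance matrix (or [rmsd_matrix()]) the clustering was built on.
#' @param result a [average_linkage_cluster()] result.
#' @return integer vector, one frame index per cluster.
#' @export
representatives <- function(mat, result) {
  d <- if (inherits(mat, "rmsd_matrix")) mat$values else as.matrix(mat)
  vapply(seq_len(result$n_clusters), function(k) {
    m <- which(result$labels == k)
    if (length(m) == 1L) return(m)
    avg <- rowMeans(d[m, m, drop = FALSE]) * length(m) / (length(m) - 1L)
    m[which.min(avg)]
  }, integer(1))
}

#' Cluster counts across a sweep of cutoffs
#'
#' Robustness curve for the cluster-count flexibility metric: the count is
#' recomputed at each cutoff so that a naive-vs-matured ordering can be
#' checked for stability under the cutoff choice.
#'
#' @param mat distance matrix or [rmsd_matrix()].
#' @param cutoffs strictly increasing cutoffs (Angstrom).
#' @return data.frame with columns `cutoff` and `n_clusters`.
#' @export
cluster_count_sweep <- function(mat, cutoffs) {
  if (is.unsorted(cutoffs, strictly = TRUE)) stop("cutoffs must be strictly increasing")
  data.frame(cutoff = cutoffs,
             n_clusters = vapply(cutoffs, function(ct)
               average_linkage_cluster(mat, ct)$n_clusters, integer(1)))
}
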