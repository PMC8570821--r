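#' Clustering parameters
#'
#' @param mode \code{"maxclust"} cuts the dendrogram into a fixed number of
#'   clusters (bounding the representative count per generation);
#'   \code{"threshold"} cuts at an RMSD height.
#' @param maxclust requested cluster count (maxclust mode); the effective
#'   count is \code{min(maxclust, M)}.
#' @param threshold RMSD cut in Angstrom (threshold mode).
#' @param linkage agglomeration rule: \code{"average"}, \code{"complete"} or
#'   \code{"ward"}.
#' @return a list of class \code{"ClusterParams"}.
#' @export
cluster_params <- function(mode = c("maxclust", "threshold"), maxclust = 60L,
                           threshold = NULL,
                           linkage = c("average", "complete", "ward")) {
  mode <- match.arg(mode)
  linkage <- match.arg(linkage)
  maxclust <- as.integer(maxclust)
  if (is.na(maxclust) || maxclust < 1L)
    stop("maxclust must be >= 1", call. = FALSE)
  if (mode == "threshold" && (!is.numeric(threshold) || threshold <= 0))
    stop("threshold mode needs a positive RMSD threshold", call. = FALSE)
  structure(list(mode = mode, maxclust = maxclust, threshold = threshold,
                 linkage = linkage),
            class = "ClusterParams")
}

#' Pairwise superposed C-alpha RMSD matrix
#'
#' Entry (i, j) is the minimum C-alpha RMSD between conformers i and j after
#' optimal rigid superposition (Kabsch rotation + translation, proper
#' rotation enforced).  Symmetric with zero diagonal; a metric on conformer
#' space.
#'
#' @param ens an \code{Ensemble}.
#' @param calpha_mask logical mask of the atoms entering the RMSD (>= 3).
#' @return M x M numeric matrix, Angstrom.
#' @export
pairwise_rmsd <- function(ens, calpha_mask) {
  stopifnot(inherits(ens, "Ensemble"))
  idx <- mask_indices(calpha_mask, "C-alpha mask")
  if (length(idx) < 3L)
    stop("pairwise RMSD needs at least 3 selected atoms", call. = FALSE)
  M <- n_conformers(ens)
  X <- aperm(ens$coords[, idx, , drop = FALSE], c(2L, 3L, 1L))
  pairwise_rmsd_cpp(X)
}

#' Hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering (\code{stats::hclust}) with the configured
#' linkage; the dendrogram is cut either into \code{min(maxclust, M)}
#' clusters or at the RMSD threshold.
#'
#' @param dist_mat symmetric non-negative M x M matrix with zero diagonal,
#'   e.g. from [pairwise_rmsd()].
#' @param params a \code{ClusterParams}.
#' @return a \code{ClusterResult}: list with \code{labels} (length M, ids
#'   1..K), \code{sizes} (length K) and \code{representatives} (NULL until
#'   [representatives()] fills it).
#' @export
cluster_conformers <- function(dist_mat, params = cluster_params()) {
  dist_mat <- as.matrix(dist_mat)
  M <- nrow(dist_mat)
  if (M != ncol(dist_mat) ||
      !isTRUE(all.equal(dist_mat, t(dist_mat), tolerance = 1e-8)) ||
      any(dist_mat < 0))
    stop("dist_mat must be a symmetric non-negative square matrix",
         call. = FALSE)
  if (M == 1L) {
    labels <- 1L
  } else {
    method <- switch(params$linkage, average = "average",
                     complete = "complete", ward = "ward.D2")
    hc <- stats::hclust(stats::as.dist(dist_mat), method = method)
    labels <- if (params$mode == "maxclust")
      stats::cutree(hc, k = min(params$maxclust, M))
    else
      stats::cutree(hc, h = params$threshold)
  }
  labels <- as.integer(labels)
  structure(list(labels = labels,
                 sizes = as.integer(table(labels)),
                 representatives = NULL),
            class = "ClusterResult")
}

#' Medoid representatives per cluster
#'
#' For each cluster, the member minimizing the sum of distances to all
#' members of its cluster; ties are broken by the lowest conformer index.
#'
#' @param dist_mat the distance matrix used for clustering.
#' @param result a \code{ClusterResult} with labels assigned.
#' @return the \code{ClusterResult} with \code{representatives} filled
#'   (length K, representative k belongs to cluster k).
#' @export
representatives <- function(dist_mat, result) {
  stopifnot(inherits(result, "ClusterResult"))
  dist_mat <- as.matrix(dist_mat)
  labels <- result$labels
  K <- max(labels)
  reps <- integer(K)
  for (k in seq_len(K)) {
    members <- which(labels == k)
    sums <- rowSums(dist_mat[members, members, drop = FALSE])
    reps[k] <- members[which.min(sums)]   # which.min takes the first tie
  }
  result$representatives <- reps
  result
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: %d conformers in %d cluster(s)\n",
              length(x$labels), max(x$labels)))
  if (!is.null(x$representatives))
    cat("representatives:", x$representatives, "\n")
  invisible(x)
}

#' Write a distance matrix as a plain-text square matrix file
#' @param dist_mat M x M matrix.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_distance_matrix <- function(dist_mat, path) {
  utils::write.table(as.matrix(dist_mat), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
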