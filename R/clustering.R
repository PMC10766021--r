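#' Default clustering configuration
#'
#' Constants for the two-stage spatial clustering: agglomeration threshold
#' 300 pixels, random subsample cap 10,000 tumor cells, fixed default seed
#' so whole-pipeline runs are reproducible.
#'
#' @param distance_threshold_px agglomeration threshold in pixels.
#' @param subsample_max maximum number of tumor cells clustered directly;
#'   the remainder is assigned by the nearest-neighbor rule.
#' @param seed integer seed for the subsample draw.
#' @return Named list.
#' @export
clustering_config <- function(distance_threshold_px = 300,
                              subsample_max = 10000,
                              seed = 1L) {
  if (distance_threshold_px <= 0)
    ki67cl_stop("config", "distance_threshold_px must be positive")
  if (subsample_max <= 0)
    ki67cl_stop("config", "subsample_max must be positive")
  list(distance_threshold_px = distance_threshold_px,
       subsample_max = as.integer(subsample_max),
       seed = as.integer(seed))
}

#' Draw the random clustering subsample
#'
#' Splits the tumor cells into a uniform random subset of at most `max_n`
#' cells (clustered directly) and the remainder (assigned afterwards by the
#' nearest-neighbor rule). When the input has at most `max_n` cells the
#' subset is all of them and the result is seed-independent.
#'
#' @param points n x 2 matrix/data.frame of tumor-cell coordinates.
#' @param max_n subsample cap (default 10000).
#' @param seed integer seed.
#' @return list with sorted integer index vectors `subset` and `remainder`
#'   (disjoint; their union is `1:n`).
#' @export
subsample_cells <- function(points, max_n = 10000, seed = 1L) {
  if (max_n <= 0) ki67cl_stop("config", "max_n must be positive")
  n <- nrow(as_points(points))
  if (n <= max_n)
    return(list(subset = seq_len(n), remainder = integer(0)))
  idx <- sort(with_seed(seed, sample.int(n, max_n)))
  list(subset = idx, remainder = setdiff(seq_len(n), idx))
}

#' Agglomerative clustering of cell centroids
#'
#' Bottom-up hierarchical clustering with Euclidean distance and unweighted
#' average linkage (UPGMA). Merging proceeds while the smallest
#' between-cluster average distance is strictly below `distance_threshold`;
#' the first merge at or above the threshold does not happen. A single point
#' yields one cluster.
#'
#' @param points n x 2 matrix/data.frame of coordinates (n >= 1).
#' @param distance_threshold agglomeration threshold in pixels (default 300).
#' @return Object of class `"cluster_assignment"`: list with `cluster_id`
#'   (integer vector, ids contiguous `1..C`, aligned with `points` rows) and
#'   `n_clusters`.
#' @export
agglomerate <- function(points, distance_threshold = 300) {
  pts <- as_points(points)
  if (nrow(pts) == 0L)
    ki67cl_stop("empty_input", "cannot cluster zero points")
  if (distance_threshold <= 0)
    ki67cl_stop("config", "distance threshold must be positive")
  n <- nrow(pts)
  if (n == 1L) return(new_cluster_assignment(1L))
  hc <- stats::hclust(stats::dist(pts), method = "average")
  below <- hc$height < distance_threshold
  labels <- if (any(below)) {
    stats::cutree(hc, h = max(hc$height[below]))
  } else {
    seq_len(n)
  }
  new_cluster_assignment(as.integer(labels))
}

new_cluster_assignment <- function(cluster_id) {
  # relabel to contiguous ids in order of first appearance
  ids <- as.integer(factor(cluster_id, levels = unique(cluster_id)))
  structure(list(cluster_id = ids, n_clusters = max(ids)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d cells in %d cluster(s)\n",
              length(x$cluster_id), x$n_clusters))
  invisible(x)
}

#' Assign remaining cells to existing clusters by nearest neighbor
#'
#' Each remainder cell receives the cluster id of its Euclidean-nearest
#' clustered cell; exact distance ties break toward the lowest cluster id.
#' Computed in blocks so large slides never materialize a full distance
#' matrix.
#'
#' @param remainder r x 2 coordinates of unassigned cells.
#' @param clustered s x 2 coordinates of already-clustered cells (s >= 1).
#' @param assignment [agglomerate()] result aligned with `clustered`.
#' @return Integer vector of cluster ids for the remainder cells.
#' @export
assign_remainder <- function(remainder, clustered, assignment) {
  rem <- as_points(remainder); clu <- as_points(clustered)
  if (nrow(clu) == 0L)
    ki67cl_stop("empty_input", "no clustered cells to assign against")
  if (nrow(rem) == 0L) return(integer(0))
  ids <- assignment$cluster_id
  out <- integer(nrow(rem))
  block <- 512L
  for (b0 in seq(1L, nrow(rem), by = block)) {
    b1 <- min(b0 + block - 1L, nrow(rem))
    d <- cross_dist(rem[b0:b1, , drop = FALSE], clu)
    out[b0:b1] <- apply(d, 1L, function(row) {
      nearest <- which(row <= min(row))   # all exact ties
      min(ids[nearest])
    })
  }
  out
}

#' Cluster the tumor cells of a slide
#'
#' The full two-stage procedure: restrict to tumor-class cells, draw the
#' seeded random subsample, agglomerate it at the distance threshold, then
#' assign the remaining tumor cells to the resulting clusters by the
#' nearest-neighbor rule.
#'
#' @param cells a [cell_table()] with at least one tumor cell.
#' @param config a [clustering_config()].
#' @param seed optional override of the config seed.
#' @return Object of class `"cluster_assignment"` with an extra field
#'   `tumor_index`: the rows of `cells` (tumor cells, original order) that
#'   `cluster_id` is aligned with.
#' @export
cluster_tumor_cells <- function(cells, config = clustering_config(),
                                seed = config$seed) {
  tumor_rows <- which(cells$cell_class %in% TUMOR_CLASSES)
  if (length(tumor_rows) == 0L)
    ki67cl_stop("unscorable", "slide '%s' has no tumor cells", slide_id(cells))
  pts <- as.matrix(cells[tumor_rows, c("x", "y")])
  split <- subsample_cells(pts, max_n = config$subsample_max, seed = seed)
  base <- agglomerate(pts[split$subset, , drop = FALSE],
                      distance_threshold = config$distance_threshold_px)
  ids <- integer(nrow(pts))
  ids[split$subset] <- base$cluster_id
  if (length(split$remainder))
    ids[split$remainder] <- assign_remainder(
      pts[split$remainder, , drop = FALSE],
      pts[split$subset, , drop = FALSE], base)
  out <- new_cluster_assignment(ids)
  out$tumor_index <- tumor_rows
  out
}
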