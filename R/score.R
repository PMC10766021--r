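#' Binary Shannon entropy of a cluster's Ki67-positive fraction
#'
#' The colocalization measure for one cluster: the Shannon diversity of the
#' two tumor-cell classes, `-(p log2 p + (1 - p) log2(1 - p))` with the
#' convention `0 log2 0 = 0`. It is 0 when the cluster holds a single class
#' and peaks at 1 when both classes are equally represented.
#'
#' @param p_plus fraction of Ki67-positive tumor cells in the cluster,
#'   in `[0, 1]` (vectorized).
#' @return Entropy in bits, in `[0, 1]`.
#' @examples
#' cluster_entropy(c(0, 0.25, 0.5, 1))
#' @export
cluster_entropy <- function(p_plus) {
  if (any(!is.finite(p_plus)) || any(p_plus < 0) || any(p_plus > 1))
    ki67cl_stop("fraction", "p_plus must lie in [0, 1]")
  term <- function(p) ifelse(p == 0, 0, p * log2(p))
  -(term(p_plus) + term(1 - p_plus))
}

#' Per-cluster Ki67 composition statistics
#'
#' @param cells a [cell_table()].
#' @param assignment a [cluster_tumor_cells()] result for `cells`.
#' @return data.frame with one row per cluster: `cluster_id`, `n_pos`,
#'   `n_neg`, `p_plus`, `entropy`.
#' @export
cluster_stats <- function(cells, assignment) {
  cls <- cells$cell_class[assignment$tumor_index]
  ids <- assignment$cluster_id
  n_pos <- tapply(cls == "TUMOR_POS", ids, sum)
  n_neg <- tapply(cls == "TUMOR_NEG", ids, sum)
  cid <- as.integer(names(n_pos))
  p <- as.numeric(n_pos) / (as.numeric(n_pos) + as.numeric(n_neg))
  out <- data.frame(cluster_id = cid,
                    n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                    p_plus = p, entropy = cluster_entropy(p))
  out[order(out$cluster_id), , drop = FALSE]
}

#' Slide-level Ki67CL score from cluster statistics
#'
#' The unweighted arithmetic mean of the per-cluster binary Shannon
#' entropies, `(1 / C) * sum_i H(p_i+)`. Clusters are weighted equally
#' regardless of size, exactly as the score is defined. The result is in
#' `[0, 1]`: 0 when every cluster is pure, 1 when every cluster is exactly
#' balanced.
#'
#' @param stats data.frame from [cluster_stats()] (needs columns `p_plus` or
#'   `entropy`).
#' @return The Ki67CL score, unitless in `[0, 1]`.
#' @export
ki67cl_score <- function(stats) {
  if (nrow(stats) == 0L)
    ki67cl_stop("unscorable", "no clusters: cannot score slide")
  ent <- if ("entropy" %in% names(stats)) stats$entropy
         else cluster_entropy(stats$p_plus)
  mean(ent)
}

#' AutoKi67 positivity ratio
#'
#' The conventional automated Ki67 score: the fraction of Ki67-positive
#' tumor cells among all tumor cells. Nontumor cells are ignored.
#'
#' @param cells a [cell_table()] with at least one tumor cell.
#' @return Fraction in `[0, 1]`.
#' @export
autoki67_ratio <- function(cells) {
  n_pos <- sum(cells$cell_class == "TUMOR_POS")
  n_neg <- sum(cells$cell_class == "TUMOR_NEG")
  if (n_pos + n_neg == 0L)
    ki67cl_stop("unscorable", "slide '%s' has no tumor cells", slide_id(cells))
  n_pos / (n_pos + n_neg)
}

#' Score one slide
#'
#' Composes the whole pipeline for one slide: optional region filtering
#' under the chosen setting, two-stage spatial clustering of tumor cells,
#' per-cluster entropies, the Ki67CL score and the AutoKi67 ratio. When
#' regions are supplied the AutoKi67 ratio always uses the invasive tumor
#' region (`WITHOUT_DCIS`) cell set, as conventional Ki67 scoring does;
#' without regions it falls back to all tumor cells.
#'
#' @param cells a [cell_table()].
#' @param regions optional [region_set()].
#' @param setting region setting for the Ki67CL score, `"WITH_DCIS"` or
#'   `"WITHOUT_DCIS"`; ignored when `regions` is `NULL`.
#' @param config a [clustering_config()].
#' @param seed seed for the clustering subsample (default from config).
#' @return Object of class `"slide_score"`: list with `slide_id`, `ki67cl`,
#'   `autoki67`, `n_clusters`, `n_tumor_cells`, `region_setting`, `seed`.
#' @export
score_slide <- function(cells, regions = NULL,
                        setting = c("WITHOUT_DCIS", "WITH_DCIS"),
                        config = clustering_config(), seed = config$seed) {
  setting <- match.arg(setting)
  sid <- slide_id(cells)
  score_cells <- cells
  auto_cells <- cells
  applied <- "NONE"
  if (!is.null(regions)) {
    score_cells <- filter_cells_by_region(cells, regions, setting)
    auto_cells <- filter_cells_by_region(cells, regions, "WITHOUT_DCIS")
    applied <- setting
  }
  if (nrow(score_cells) == 0L)
    ki67cl_stop("unscorable", "slide '%s': no cells left after region filtering", sid)
  assignment <- cluster_tumor_cells(score_cells, config = config, seed = seed)
  stats <- cluster_stats(score_cells, assignment)
  structure(list(slide_id = sid,
                 ki67cl = ki67cl_score(stats),
                 autoki67 = autoki67_ratio(auto_cells),
                 n_clusters = assignment$n_clusters,
                 n_tumor_cells = length(assignment$tumor_index),
                 region_setting = applied,
                 seed = as.integer(seed)),
            class = "slide_score")
}

#' @export
print.slide_score <- function(x, ...) {
  cat(sprintf(
    "<slide_score> '%s' (%s): Ki67CL = %.4f, AutoKi67 = %.4f (%d clusters, %d tumor cells)\n",
    x$slide_id, x$region_setting, x$ki67cl, x$autoki67,
    x$n_clusters, x$n_tumor_cells))
  invisible(x)
}

#' Collect slide scores into a data.frame
#' @param scores list of [score_slide()] results.
#' @return data.frame with one row per slide.
#' @export
scores_to_df <- function(scores) {
  do.call(rbind, lapply(scores, function(s)
    data.frame(slide_id = s$slide_id, ki67cl = s$ki67cl,
               autoki67 = s$autoki67, n_clusters = s$n_clusters,
               n_tumor_cells = s$n_tumor_cells,
               region_setting = s$region_setting, seed = s$seed,
               stringsAsFactors = FALSE)))
}
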