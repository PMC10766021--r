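#' Match predicted detections to ground-truth dots
#'
#' One-to-one matching between predicted and annotated cell centroids.
#' Following the agreement rule used for dot annotations, two centroids
#' within `radius` pixels count as the same cell. Among all one-to-one
#' pairings restricted to pairs within the radius, the matching maximizes
#' the number of pairs and, among those, minimizes the total distance
#' (optimal bipartite assignment), so the evaluation is deterministic.
#'
#' @param predictions n x 2 matrix or data.frame of predicted (x, y).
#' @param truths m x 2 matrix or data.frame of ground-truth (x, y).
#' @param radius match radius in pixels (default 20).
#' @return An object of class `"match_result"`: a list with `pairs` (a
#'   data.frame with columns `prediction`, `truth`, `distance`),
#'   `unmatched_predictions` and `unmatched_truths` (integer index vectors),
#'   and the counts `n_predictions`, `n_truths`.
#' @examples
#' match_detections(cbind(0, 0), cbind(0, 19))$pairs   # within 20 px: matched
#' match_detections(cbind(0, 0), cbind(0, 21))$pairs   # beyond 20 px: empty
#' @export
match_detections <- function(predictions, truths, radius = 20) {
  if (radius <= 0) ki67cl_stop("radius", "match radius must be positive")
  p <- as_points(predictions); t <- as_points(truths)
  n <- nrow(p); m <- nrow(t)
  empty <- data.frame(prediction = integer(0), truth = integer(0),
                      distance = numeric(0))
  res <- list(pairs = empty,
              unmatched_predictions = seq_len(n),
              unmatched_truths = seq_len(m),
              n_predictions = n, n_truths = m)
  class(res) <- "match_result"
  if (n == 0L || m == 0L) return(res)

  d <- cross_dist(p, t)
  edges <- which(d <= radius, arr.ind = TRUE)
  if (nrow(edges) == 0L) return(res)
  ei <- edges[, 1]; ej <- edges[, 2]; ec <- d[edges]

  # Min-cost maximum-cardinality bipartite matching by successive shortest
  # augmenting paths (Bellman-Ford on the residual graph; edge costs are the
  # pair distances, so each cardinality is achieved at minimum total distance).
  match_p <- rep(NA_integer_, n)
  match_t <- rep(NA_integer_, m)
  tol <- 1e-9
  repeat {
    dp <- ifelse(is.na(match_p), 0, Inf)
    dt <- rep(Inf, m)
    prev_t <- rep(NA_integer_, m)
    repeat {
      changed <- FALSE
      # relax non-matching edges pred -> truth
      cand <- dp[ei] + ec
      ok <- which(cand < dt[ej] - tol & !(match_p[ei] == ej & !is.na(match_p[ei])))
      for (k in ok) {
        j <- ej[k]
        if (cand[k] < dt[j] - tol) {
          dt[j] <- cand[k]; prev_t[j] <- ei[k]; changed <- TRUE
        }
      }
      # relax matching edges truth -> pred (residual, negative cost)
      mi <- which(!is.na(match_p))
      for (i in mi) {
        j <- match_p[i]
        if (dt[j] - d[i, j] < dp[i] - tol) {
          dp[i] <- dt[j] - d[i, j]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    free_t <- which(is.na(match_t) & is.finite(dt))
    if (length(free_t) == 0L) break
    jstar <- free_t[which.min(dt[free_t])]
    # augment backwards along predecessor pointers
    j <- jstar
    repeat {
      i <- prev_t[j]
      oldj <- match_p[i]
      match_p[i] <- j; match_t[j] <- i
      if (is.na(oldj)) break
      j <- oldj
    }
  }

  mi <- which(!is.na(match_p))
  pairs <- data.frame(prediction = mi, truth = match_p[mi],
                      distance = d[cbind(mi, match_p[mi])])
  pairs <- pairs[order(pairs$prediction), , drop = FALSE]
  rownames(pairs) <- NULL
  res$pairs <- pairs
  res$unmatched_predictions <- setdiff(seq_len(n), pairs$prediction)
  res$unmatched_truths <- setdiff(seq_len(m), pairs$truth)
  res
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pairs (%d predictions, %d truths)\n",
              nrow(x$pairs), x$n_predictions, x$n_truths))
  invisible(x)
}

#' Detection and classification agreement metrics
#'
#' Evaluates a matching against ground truth. Precision, recall and F1 are
#' computed over detection pairs regardless of class; accuracy and Cohen's
#' kappa over the class labels of matched pairs only; Spearman's rho over
#' per-patch, per-class count vectors when patch assignments are supplied.
#'
#' @param match a [match_detections()] result.
#' @param pred_classes,truth_classes class labels aligned with the point
#'   lists used for matching.
#' @param pred_patch,truth_patch optional patch identifiers per point;
#'   required for the Spearman statistic.
#' @return Named list: `precision`, `recall`, `f1`, `accuracy`, `kappa`,
#'   `spearman`. With zero matched pairs, `accuracy` and `kappa` are `NA`
#'   (undefined, not zero); `spearman` is `NA` when patches are absent.
#' @export
detection_metrics <- function(match, pred_classes, truth_classes,
                              pred_patch = NULL, truth_patch = NULL) {
  if (length(pred_classes) != match$n_predictions ||
      length(truth_classes) != match$n_truths)
    ki67cl_stop("metrics", "class labels must align with the matched point lists")
  npair <- nrow(match$pairs)
  precision <- if (match$n_predictions > 0) npair / match$n_predictions else NA_real_
  recall <- if (match$n_truths > 0) npair / match$n_truths else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0)
    2 * precision * recall / (precision + recall) else 0
  if (npair > 0) {
    a <- pred_classes[match$pairs$prediction]
    b <- truth_classes[match$pairs$truth]
    lev <- union(a, b)
    cm <- table(factor(a, lev), factor(b, lev))
    po <- sum(diag(cm)) / npair
    pe <- sum(rowSums(cm) * colSums(cm)) / npair^2
    accuracy <- po
    kappa <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
  } else {
    accuracy <- NA_real_
    kappa <- NA_real_
  }
  spearman <- NA_real_
  if (!is.null(pred_patch) && !is.null(truth_patch)) {
    patches <- union(unique(pred_patch), unique(truth_patch))
    classes <- union(unique(pred_classes), unique(truth_classes))
    cnt <- function(patch, cls) as.vector(table(
      factor(patch, patches), factor(cls, classes)))
    vp <- cnt(pred_patch, pred_classes)
    vt <- cnt(truth_patch, truth_classes)
    if (stats::sd(vp) > 0 && stats::sd(vt) > 0)
      spearman <- stats::cor(vp, vt, method = "spearman")
  }
  list(precision = precision, recall = recall, f1 = f1,
       accuracy = accuracy, kappa = kappa, spearman = spearman)
}
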