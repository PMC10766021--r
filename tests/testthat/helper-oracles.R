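# Independent brute-force oracles used across the suite. Each re-derives the
# quantity from first principles by a different route than the implementation.

# Textbook O(n^3) average-linkage agglomeration: explicit cluster list,
# between-cluster distance recomputed as the mean of all pairwise distances,
# merge while the minimum is strictly below the threshold.
oracle_average_linkage <- function(pts, threshold) {
  n <- nrow(pts)
  clusters <- as.list(seq_len(n))
  d <- as.matrix(stats::dist(pts))
  repeat {
    if (length(clusters) == 1L) break
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      avg <- mean(d[clusters[[a]], clusters[[b]]])
      if (avg < best_d) { best_d <- avg; best <- c(a, b) }
    }
    if (best_d >= threshold) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
  labels
}

# Partitions as canonical strings for label-invariant comparison.
partition_key <- function(labels) {
  paste(vapply(split(seq_along(labels), labels), paste, character(1),
               collapse = ","), collapse = "|")
}

# Exhaustive one-to-one matching: maximize pair count, then minimize total
# distance, by recursion over all injective partial assignments.
oracle_match <- function(pred, truth, radius) {
  d <- ki67cl:::cross_dist(pred, truth)
  n <- nrow(pred); m <- nrow(truth)
  best <- list(count = -1L, cost = Inf, pairs = NULL)
  recurse <- function(i, used, pairs, cost) {
    if (i > n) {
      cnt <- nrow(pairs)
      if (cnt > best$count || (cnt == best$count && cost < best$cost - 1e-12))
        best <<- list(count = cnt, cost = cost, pairs = pairs)
      return(invisible())
    }
    recurse(i + 1L, used, pairs, cost)                 # leave prediction i out
    for (j in seq_len(m)) {
      if (used[j] || d[i, j] > radius) next
      recurse(i + 1L, replace(used, j, TRUE),
              rbind(pairs, data.frame(prediction = i, truth = j)),
              cost + d[i, j])
    }
  }
  recurse(1L, rep(FALSE, m),
          data.frame(prediction = integer(0), truth = integer(0)), 0)
  best
}

# Even-odd point-in-polygon with a *vertical* ray (the implementation casts
# horizontally), boundary handled by segment-distance check.
oracle_point_in_rings <- function(px, py, rings) {
  on_segment <- function(px, py, x1, y1, x2, y2) {
    L2 <- (x2 - x1)^2 + (y2 - y1)^2
    t <- if (L2 == 0) 0 else ((px - x1) * (x2 - x1) + (py - y1) * (y2 - y1)) / L2
    t <- min(1, max(0, t))
    qx <- x1 + t * (x2 - x1); qy <- y1 + t * (y2 - y1)
    sqrt((px - qx)^2 + (py - qy)^2) < 1e-9
  }
  inside <- FALSE
  for (ring in rings) {
    nv <- nrow(ring)
    for (k in seq_len(nv)) {
      k2 <- if (k == nv) 1L else k + 1L
      x1 <- ring[k, 1]; y1 <- ring[k, 2]; x2 <- ring[k2, 1]; y2 <- ring[k2, 2]
      if (on_segment(px, py, x1, y1, x2, y2)) return(TRUE)
      if ((x1 > px) != (x2 > px)) {
        yint <- y1 + (px - x1) * (y2 - y1) / (x2 - x1)
        if (py < yint) inside <- !inside
      }
    }
  }
  inside
}

# Harrell's C by exhaustive pair enumeration (higher marker = worse).
oracle_concordance <- function(time, event, marker) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # identify the pair member with the definitely shorter survival
    if (time[i] == time[j]) {
      if (event[i] == event[j]) next           # tied times, same status: not comparable
      short <- if (event[i] == 1) i else j
    } else {
      short <- if (time[i] < time[j]) i else j
      if (event[short] == 0) next              # shorter time censored: not comparable
    }
    long <- setdiff(c(i, j), short)
    den <- den + 1
    if (marker[short] > marker[long]) num <- num + 1
    else if (marker[short] == marker[long]) num <- num + 0.5
  }
  if (den == 0) NA_real_ else num / den
}

# Greedy suppression by descending probability: the reference behavior of the
# "closer than r keeps the strongest" merge rule.
oracle_suppress <- function(df, radius) {
  df <- df[order(-df$probability, df$chan_rank, df$y, df$x), , drop = FALSE]
  kept <- df[0, ]
  for (k in seq_len(nrow(df))) {
    if (nrow(kept) == 0 ||
        all((kept$x - df$x[k])^2 + (kept$y - df$y[k])^2 >= radius^2))
      kept <- rbind(kept, df[k, ])
  }
  kept
}

# Exact blob table: widely separated blobs with prescribed per-blob class mix.
make_blob_table <- function(pos_per_blob, neg_per_blob, n_blobs = 3,
                            spacing = 2000, sigma = 15, seed = 42) {
  withr::with_seed(seed, {
    xs <- ys <- numeric(0); cls <- character(0)
    for (b in seq_len(n_blobs) - 1L) {
      n <- pos_per_blob + neg_per_blob
      xs <- c(xs, pmax(0, rnorm(n, 200 + b * spacing, sigma)))
      ys <- c(ys, pmax(0, rnorm(n, 200, sigma)))
      cls <- c(cls, rep("TUMOR_POS", pos_per_blob), rep("TUMOR_NEG", neg_per_blob))
    }
    cell_table(xs, ys, cls, slide_id = "blob")
  })
}
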