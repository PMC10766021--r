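#' Tile an image extent into patches
#'
#' Non-overlapping grid of windows covering the full `height` x `width`
#' extent; interior windows are `patch` x `patch` pixels and edge windows
#' are clipped. Windows are half-open pixel intervals in 0-based
#' coordinates: a window covers columns `[x0, x0 + w)` and rows
#' `[y0, y0 + h)`.
#'
#' @param height,width image extent in pixels.
#' @param patch patch side in pixels (default 252).
#' @return data.frame with columns `x0`, `y0`, `w`, `h`, one row per window.
#' @export
tile_patches <- function(height, width, patch = 252) {
  if (patch <= 0) ki67cl_stop("patch", "patch size must be positive")
  if (height <= 0 || width <= 0)
    ki67cl_stop("patch", "image extent must be positive")
  x0 <- seq(0, width - 1, by = patch)
  y0 <- seq(0, height - 1, by = patch)
  g <- expand.grid(x0 = x0, y0 = y0)
  g$w <- pmin(patch, width - g$x0)
  g$h <- pmin(patch, height - g$y0)
  g
}

#' Construct a dot set
#'
#' Point annotations (cell centers) for one class channel within a patch.
#'
#' @param points n x 2 matrix/data.frame of 0-based (x, y) pixel coordinates.
#' @param channel class label of the channel.
#' @return Object of class `"dot_set"`.
#' @export
dot_set <- function(points, channel) {
  structure(list(points = as_points(points), channel = as.character(channel)),
            class = "dot_set")
}

#' Rasterize dot annotations into a Gaussian density label
#'
#' Convolves the binary dot image with a truncated, peak-normalized Gaussian
#' kernel: the regression target used to train center-of-cell probability
#' maps. The kernel maximum is 1 so an isolated dot produces a unit peak,
#' directly comparable to a `[0, 1]` probability map.
#'
#' @param dots a [dot_set()].
#' @param shape `c(height, width)` of the output grid in pixels.
#' @param sigma Gaussian standard deviation in pixels (default 3; kept below
#'   half the 15-px merge radius so adjacent nuclei remain separable).
#' @param truncate kernel support radius in sigmas (default 4).
#' @return `height` x `width` numeric matrix; element `[y + 1, x + 1]` is the
#'   density at 0-based pixel (x, y).
#' @export
dots_to_density <- function(dots, shape, sigma = 3, truncate = 4) {
  if (sigma <= 0) ki67cl_stop("sigma", "sigma must be positive")
  h <- shape[1]; w <- shape[2]
  grid <- matrix(0, nrow = h, ncol = w)
  pts <- dots$points
  if (nrow(pts) == 0L) return(grid)
  if (any(pts[, 1] < 0 | pts[, 1] >= w | pts[, 2] < 0 | pts[, 2] >= h))
    ki67cl_stop("dot_bounds", "dot annotation outside the patch bounds")
  r <- ceiling(truncate * sigma)
  off <- seq(-r, r)
  kern <- exp(-(outer(off^2, off^2, "+")) / (2 * sigma^2))  # peak value 1
  for (k in seq_len(nrow(pts))) {
    cx <- round(pts[k, 1]); cy <- round(pts[k, 2])
    rows <- (cy - r):(cy + r) + 1L
    cols <- (cx - r):(cx + r) + 1L
    rok <- rows >= 1L & rows <= h
    cok <- cols >= 1L & cols <= w
    grid[rows[rok], cols[cok]] <- grid[rows[rok], cols[cok]] +
      kern[rok, cok, drop = FALSE]
  }
  grid
}

#' Construct a multi-channel probability map
#'
#' @param channels named list of equally sized numeric matrices with values
#'   in `[0, 1]`, one per cell class.
#' @return Object of class `"prob_map"` with fields `channels`, `height`,
#'   `width`.
#' @export
prob_map <- function(channels) {
  if (length(channels) == 0L || is.null(names(channels)))
    ki67cl_stop("prob_map", "channels must be a named non-empty list")
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1L)
    ki67cl_stop("prob_map", "all channels must share one grid shape")
  for (ch in channels) {
    if (any(!is.finite(ch)) || any(ch < 0) || any(ch > 1))
      ki67cl_stop("prob_map", "channel values must be finite and in [0, 1]")
  }
  structure(list(channels = channels,
                 height = dims[[1]][1], width = dims[[1]][2]),
            class = "prob_map")
}

#' @export
print.prob_map <- function(x, ...) {
  cat(sprintf("<prob_map> %d x %d px, %d channel(s): %s\n",
              x$height, x$width, length(x$channels),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Find local maxima of a probability channel
#'
#' Candidate cell centers are pixels whose value is at least
#' `min_probability` and maximal within a Euclidean `min_distance`
#' neighborhood; plateaus yield one representative (lowest row, then lowest
#' column). Retained maxima are additionally mutually at least
#' `min_distance` apart (suppression in decreasing probability order).
#'
#' @param map_channel numeric matrix with values in `[0, 1]`.
#' @param min_probability detection threshold (default 0.5).
#' @param min_distance neighborhood radius in pixels (default 15).
#' @return data.frame with columns `x`, `y` (0-based pixel coordinates) and
#'   `probability`, ordered by decreasing probability.
#' @export
find_local_maxima <- function(map_channel, min_probability = 0.5,
                              min_distance = 15) {
  h <- nrow(map_channel); w <- ncol(map_channel)
  idx <- which(map_channel >= min_probability)
  if (length(idx) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), probability = numeric(0)))
  ry <- (idx - 1L) %% h        # 0-based row (y)
  rx <- (idx - 1L) %/% h       # 0-based column (x)
  v <- map_channel[idx]
  r <- floor(min_distance)
  keep <- logical(length(idx))
  for (k in seq_along(idx)) {
    y0 <- ry[k]; x0 <- rx[k]; val <- v[k]
    ys <- max(0, y0 - r):min(h - 1, y0 + r)
    xs <- max(0, x0 - r):min(w - 1, x0 + r)
    sub <- map_channel[ys + 1L, xs + 1L, drop = FALSE]
    dy <- outer(ys - y0, rep(1, length(xs)))
    dx <- outer(rep(1, length(ys)), xs - x0)
    near <- (dx * dx + dy * dy) <= min_distance^2
    if (any(sub[near] > val)) next
    # plateau: representative is the first equal-valued pixel in (row, col) order
    eq <- near & (sub == val)
    eqy <- dy[eq] + y0; eqx <- dx[eq] + x0
    first <- order(eqy, eqx)[1]
    if (eqy[first] < y0 || (eqy[first] == y0 && eqx[first] < x0)) next
    keep[k] <- TRUE
  }
  out <- data.frame(x = rx[keep], y = ry[keep], probability = v[keep])
  out <- out[order(-out$probability, out$y, out$x), , drop = FALSE]
  # mutual min_distance suppression, strongest first
  if (nrow(out) > 1L) {
    sel <- integer(0)
    for (k in seq_len(nrow(out))) {
      if (length(sel)) {
        d2 <- (out$x[sel] - out$x[k])^2 + (out$y[sel] - out$y[k])^2
        if (any(d2 < min_distance^2)) next
      }
      sel <- c(sel, k)
    }
    out <- out[sel, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Merge detections across class channels
#'
#' Non-maximum suppression across channels: when several detections lie
#' strictly closer than `merge_radius` pixels to one another, only the one
#' with the highest probability is kept. Ties break by channel order, then
#' by coordinates (row, then column).
#'
#' @param per_channel named list of data.frames as returned by
#'   [find_local_maxima()], one per class channel; names give channel order.
#' @param merge_radius suppression radius in pixels (default 15; "closer
#'   than" is strict, so detections exactly `merge_radius` apart both
#'   survive).
#' @return data.frame with columns `x`, `y`, `channel`, `probability`.
#' @export
merge_channels <- function(per_channel, merge_radius = 15) {
  if (merge_radius <= 0) ki67cl_stop("radius", "merge radius must be positive")
  dfs <- lapply(names(per_channel), function(nm) {
    d <- per_channel[[nm]]
    if (nrow(d) == 0L) return(NULL)
    data.frame(x = d$x, y = d$y, channel = nm, probability = d$probability,
               chan_rank = match(nm, names(per_channel)))
  })
  all <- do.call(rbind, dfs)
  if (is.null(all) || nrow(all) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0),
                      channel = character(0), probability = numeric(0)))
  all <- all[order(-all$probability, all$chan_rank, all$y, all$x), , drop = FALSE]
  sel <- integer(0)
  for (k in seq_len(nrow(all))) {
    if (length(sel)) {
      d2 <- (all$x[sel] - all$x[k])^2 + (all$y[sel] - all$y[k])^2
      if (any(d2 < merge_radius^2)) next
    }
    sel <- c(sel, k)
  }
  out <- all[sel, c("x", "y", "channel", "probability"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full detection post-processing on a probability map
#'
#' Per-channel local-maxima extraction followed by cross-channel merging.
#'
#' @param pmap a [prob_map()].
#' @param min_probability,min_distance passed to [find_local_maxima()].
#' @param merge_radius passed to [merge_channels()].
#' @return data.frame of merged detections (`x`, `y`, `channel`,
#'   `probability`).
#' @export
detect_cells <- function(pmap, min_probability = 0.5, min_distance = 15,
                         merge_radius = 15) {
  per <- lapply(pmap$channels, find_local_maxima,
                min_probability = min_probability, min_distance = min_distance)
  merge_channels(per, merge_radius = merge_radius)
}
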