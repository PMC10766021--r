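# Internal helpers shared across modules.

#' Signal a classed error
#'
#' All user-facing failure modes raise conditions with a package-specific
#' class (`ki67cl_error_<what>`) so callers and tests can trap them by name.
#'
#' @noRd
ki67cl_stop <- function(what, msg, ...) {
  stop(structure(
    class = c(paste0("ki67cl_error_", what), "ki67cl_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Run code with a temporary RNG seed, restoring global RNG state
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Euclidean cross-distance between two point sets
#'
#' Points are n x 2 matrices (columns x, y). Returns the |a| x |b| distance
#' matrix; computed in blocks to bound memory when |a| is large.
#' @noRd
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

#' Coerce a two-column point argument to a numeric matrix
#' @noRd
as_points <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p[, c("x", "y")])
  p <- as.matrix(p)
  if (length(p) == 0L) return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("x", "y"))))
  if (ncol(p) != 2L) ki67cl_stop("points", "point input must have two columns (x, y)")
  storage.mode(p) <- "double"
  colnames(p) <- c("x", "y")
  p
}
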