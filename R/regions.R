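#' Region labels recognised in annotations
#' @format Character vector of length 3.
#' @export
REGION_LABELS <- c("TUMOR", "DCIS", "NORMAL")

#' Construct a region set
#'
#' Region annotations for one slide: labelled polygons (tumor, ductal
#' carcinoma in situ, normal) in the same 0-based pixel frame as the cell
#' table. Each region is a list of one or more closed rings; additional
#' rings are holes under the even-odd fill rule.
#'
#' @param regions list of regions, each `list(label =, rings = list of
#'   n x 2 coordinate matrices)`.
#' @param slide_id opaque slide identifier.
#' @return An object of class `"region_set"`.
#' @export
region_set <- function(regions, slide_id = "slide") {
  for (r in regions) {
    if (!r$label %in% REGION_LABELS)
      ki67cl_stop("region_label", "unknown region label '%s'", r$label)
    for (ring in r$rings) {
      ring <- as_points(ring)
      if (nrow(ring) < 3L)
        ki67cl_stop("degenerate_polygon", "polygon ring has fewer than 3 vertices")
      if (abs(ring_area(ring)) <= 0)
        ki67cl_stop("degenerate_polygon", "polygon ring has zero area")
    }
  }
  structure(list(slide_id = as.character(slide_id),
                 regions = lapply(regions, function(r)
                   list(label = r$label, rings = lapply(r$rings, as_points)))),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> slide '%s': %d region(s)\n",
              x$slide_id, length(x$regions)))
  for (lab in REGION_LABELS) {
    n <- sum(vapply(x$regions, function(r) r$label == lab, logical(1)))
    if (n) cat(sprintf("  %-6s %d\n", lab, n))
  }
  invisible(x)
}

# Signed shoelace area of one ring (closure implicit).
ring_area <- function(ring) {
  n <- nrow(ring)
  j <- c(n, seq_len(n - 1L))
  sum(ring[j, 1] * ring[, 2] - ring[, 1] * ring[j, 2]) / 2
}

#' Read region annotations from GeoJSON
#'
#' Expects a FeatureCollection of Polygon / MultiPolygon features with a
#' `label` property in [REGION_LABELS]; coordinates are pixels.
#'
#' @param path GeoJSON file path.
#' @param slide_id identifier; defaults to the file stem.
#' @return A [region_set()].
#' @export
read_regions <- function(path, slide_id = NULL) {
  if (!file.exists(path))
    ki67cl_stop("missing_file", "region file not found: %s", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features))
    ki67cl_stop("geojson", "not a GeoJSON FeatureCollection: %s", path)
  ring_mat <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    # drop the GeoJSON closing vertex; closure is implicit here
    if (nrow(m) > 1L && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  }
  regions <- list()
  for (f in gj$features) {
    lab <- f$properties$label
    geom <- f$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      ki67cl_stop("geojson", "unsupported geometry type '%s'", geom$type))
    for (poly in polys)
      regions[[length(regions) + 1L]] <-
        list(label = lab, rings = lapply(poly, ring_mat))
  }
  if (is.null(slide_id)) slide_id <- sub("\\.[^.]*$", "", basename(path))
  region_set(regions, slide_id = slide_id)
}

#' Write a region set as GeoJSON
#' @param regions a [region_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  feats <- lapply(regions$regions, function(r) {
    rings <- lapply(r$rings, function(ring) {
      ring <- rbind(ring, ring[1, , drop = FALSE])
      lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
    })
    list(type = "Feature",
         properties = list(label = r$label),
         geometry = list(type = "Polygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Even-odd point-in-polygon with boundary points counted inside.
# Horizontal ray-cast toward +x across all rings of one region.
point_in_rings <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  eps <- 1e-9
  for (ring in rings) {
    n <- nrow(ring)
    xs <- ring[, 1]; ys <- ring[, 2]
    j <- c(n, seq_len(n - 1L))
    for (k in seq_len(n)) {
      x1 <- xs[j[k]]; y1 <- ys[j[k]]; x2 <- xs[k]; y2 <- ys[k]
      # boundary: point on segment (x1,y1)-(x2,y2)
      cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
      seglen2 <- (x2 - x1)^2 + (y2 - y1)^2
      dot <- (px - x1) * (x2 - x1) + (py - y1) * (y2 - y1)
      on_edge <- on_edge |
        (abs(cross) <= eps * (1 + sqrt(seglen2)) & dot >= -eps & dot <= seglen2 + eps)
      # even-odd crossing with half-open vertex rule
      crosses <- ((y1 > py) != (y2 > py)) &
        (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
      crosses[is.na(crosses)] <- FALSE
      inside <- xor(inside, crosses)
    }
  }
  inside | on_edge
}

# Membership of cells in any region of a given label.
cells_in_label <- function(cells, regions, label) {
  hit <- rep(FALSE, nrow(cells))
  for (r in regions$regions) {
    if (r$label != label) next
    hit <- hit | point_in_rings(cells$x, cells$y, r$rings)
  }
  hit
}

#' Filter cells by annotated region
#'
#' Implements the two scoring settings: `WITH_DCIS` keeps cells inside tumor
#' or DCIS polygons (whole-slide level); `WITHOUT_DCIS` keeps cells inside
#' tumor polygons but outside every DCIS polygon (invasive tumor region
#' level). Membership uses the even-odd fill rule with boundary points
#' counted inside.
#'
#' @param cells a [cell_table()].
#' @param regions a [region_set()] in the same pixel frame.
#' @param setting `"WITH_DCIS"` or `"WITHOUT_DCIS"`.
#' @return The filtered [cell_table()] (a subset of the input rows, order
#'   preserved).
#' @export
filter_cells_by_region <- function(cells, regions,
                                   setting = c("WITHOUT_DCIS", "WITH_DCIS")) {
  setting <- match.arg(setting)
  has_tumor <- any(vapply(regions$regions, function(r) r$label == "TUMOR",
                          logical(1)))
  if (setting == "WITHOUT_DCIS" && !has_tumor)
    ki67cl_stop("no_invasive_region",
                "cannot define the invasive tumor region: no TUMOR polygons")
  in_tumor <- cells_in_label(cells, regions, "TUMOR")
  in_dcis <- cells_in_label(cells, regions, "DCIS")
  keep <- if (setting == "WITH_DCIS") in_tumor | in_dcis else in_tumor & !in_dcis
  out <- cells[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "slide_id") <- slide_id(cells)
  class(out) <- c("cell_table", "data.frame")
  out
}
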