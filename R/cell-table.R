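#' Cell class labels
#'
#' The four cell classes produced by Ki67 immunohistochemistry cell
#' classification: Ki67-positive/negative tumor cells and
#' Ki67-positive/negative nontumor cells.
#'
#' @format Character vector of length 4.
#' @export
CELL_CLASSES <- c("TUMOR_POS", "TUMOR_NEG", "NONTUMOR_POS", "NONTUMOR_NEG")

#' Tumor-cell subset of the class labels
#' @rdname CELL_CLASSES
#' @export
TUMOR_CLASSES <- c("TUMOR_POS", "TUMOR_NEG")

#' Construct a cell table
#'
#' A cell table holds one row per detected cell on one slide: pixel centroid
#' coordinates (0-based, origin top-left, x rightward, y downward, at x40
#' magnification) and one of the four class labels. Row order is preserved
#' from the source so seeded subsampling is reproducible.
#'
#' @param x,y numeric pixel coordinates, finite and non-negative.
#' @param cell_class character vector of labels in [CELL_CLASSES].
#' @param confidence optional numeric in `[0, 1]`.
#' @param slide_id opaque slide identifier.
#' @return A `data.frame` of class `"cell_table"` with columns
#'   `x`, `y`, `cell_class` and (optionally) `confidence`, and a
#'   `slide_id` attribute.
#' @examples
#' ct <- cell_table(c(0, 10), c(0, 5), c("TUMOR_POS", "TUMOR_NEG"))
#' n_tumor_cells(ct)
#' @export
cell_table <- function(x, y, cell_class, confidence = NULL, slide_id = "slide") {
  x <- as.numeric(x); y <- as.numeric(y)
  cell_class <- as.character(cell_class)
  if (length(x) != length(y) || length(x) != length(cell_class))
    ki67cl_stop("cell_table", "x, y and cell_class must have equal length")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    ki67cl_stop("coordinate", "cell coordinates must be finite")
  if (any(x < 0) || any(y < 0))
    ki67cl_stop("coordinate", "cell coordinates must be non-negative")
  bad <- setdiff(unique(cell_class), CELL_CLASSES)
  if (length(bad))
    ki67cl_stop("unknown_class", "unknown cell class label(s): %s",
                paste(bad, collapse = ", "))
  df <- data.frame(x = x, y = y, cell_class = cell_class,
                   stringsAsFactors = FALSE)
  if (!is.null(confidence)) {
    confidence <- as.numeric(confidence)
    if (length(confidence) != length(x))
      ki67cl_stop("cell_table", "confidence must match the number of cells")
    if (any(!is.na(confidence) & (confidence < 0 | confidence > 1)))
      ki67cl_stop("cell_table", "confidence must lie in [0, 1]")
    df$confidence <- confidence
  }
  attr(df, "slide_id") <- as.character(slide_id)
  class(df) <- c("cell_table", "data.frame")
  df
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> slide '%s': %d cells (%d tumor, %d nontumor)\n",
              slide_id(x), nrow(x), n_tumor_cells(x),
              nrow(x) - n_tumor_cells(x)))
  tab <- table(factor(x$cell_class, levels = CELL_CLASSES))
  print(tab)
  invisible(x)
}

#' Slide identifier of a cell table
#' @param cells a [cell_table()].
#' @return Character scalar.
#' @export
slide_id <- function(cells) attr(cells, "slide_id")

#' Number of tumor cells in a cell table
#' @param cells a [cell_table()].
#' @return Integer count of `TUMOR_POS` plus `TUMOR_NEG` cells.
#' @export
n_tumor_cells <- function(cells) sum(cells$cell_class %in% TUMOR_CLASSES)

#' Default column mapping for cell-table files
#'
#' @param slide_id,x,y,cell_class,confidence column names in the file.
#' @return Named list usable as the `dialect` of [read_cells()].
#' @export
cell_dialect <- function(slide_id = "slide_id", x = "x", y = "y",
                         cell_class = "class", confidence = "confidence") {
  list(slide_id = slide_id, x = x, y = y,
       cell_class = cell_class, confidence = confidence)
}

#' Read a cell table from delimited text
#'
#' Reads a CSV/TSV file with a header; columns are located through `dialect`
#' so arbitrary exporter column names can be mapped onto the canonical
#' schema. Unknown class labels are rejected, never coerced.
#'
#' @param path file path.
#' @param dialect column mapping from [cell_dialect()].
#' @param sep field separator; `","` for CSV, `"\t"` for TSV.
#' @return A [cell_table()].
#' @export
read_cells <- function(path, dialect = cell_dialect(), sep = ",") {
  if (!file.exists(path))
    ki67cl_stop("missing_file", "cell table file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character")
  for (col in c("x", "y", "cell_class")) {
    if (!dialect[[col]] %in% names(df))
      ki67cl_stop("missing_column", "mapped column '%s' (for %s) absent in %s",
                  dialect[[col]], col, path)
  }
  xs <- suppressWarnings(as.numeric(df[[dialect$x]]))
  ys <- suppressWarnings(as.numeric(df[[dialect$y]]))
  if (anyNA(xs) || anyNA(ys))
    ki67cl_stop("coordinate", "unparseable coordinate value in %s", path)
  sid <- if (dialect$slide_id %in% names(df) && nrow(df) > 0)
    df[[dialect$slide_id]][1] else sub("\\.[^.]*$", "", basename(path))
  conf <- if (!is.null(dialect$confidence) && dialect$confidence %in% names(df))
    suppressWarnings(as.numeric(df[[dialect$confidence]])) else NULL
  cell_table(xs, ys, df[[dialect$cell_class]], confidence = conf, slide_id = sid)
}

#' Write a cell table as CSV
#'
#' Inverse of [read_cells()] under the default dialect; a write followed by a
#' read returns an identical table.
#'
#' @param cells a [cell_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cells <- function(cells, path) {
  out <- data.frame(slide_id = slide_id(cells), x = cells$x, y = cells$y,
                    class = cells$cell_class, stringsAsFactors = FALSE)
  if ("confidence" %in% names(cells)) out$confidence <- cells$confidence
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
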