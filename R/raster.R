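#' Elevation raster
#'
#' A square-celled grid of elevations in metres: the in-memory form of a
#' digital elevation model (DEM). Values are stored as a numeric matrix whose
#' first row is the northern edge; no-data cells are `NA`. The geotransform
#' origin is the lower-left corner of the grid in metres. `gsd` records the
#' native ground sampling distance (metres per pixel) of the source model as
#' provenance metadata; it defaults to `cell_size` and is carried through
#' resampling unchanged.
#'
#' Metrics computed from an `elev_raster` are invariant to adding a constant
#' elevation, so either a positive-up or a negative-down depth convention
#' works, as long as a single file is consistent.
#'
#' @param values numeric matrix of elevations (metres); `NA` marks no-data.
#' @param cell_size cell edge length in metres (cells are square).
#' @param origin numeric length-2, `(x, y)` of the lower-left corner (metres).
#' @param gsd native ground sampling distance in metres per pixel.
#' @return An object of class `elev_raster`.
#' @examples
#' r <- elev_raster(matrix(0, 8, 8), cell_size = 0.01)
#' planform_area(r)
#' @export
elev_raster <- function(values, cell_size, origin = c(0, 0), gsd = cell_size) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_invalid("`values` must be a numeric matrix")
  if (nrow(values) < 2 || ncol(values) < 2)
    stop_invalid("elevation grid must be at least 2x2 cells")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || !is.finite(cell_size) ||
      cell_size <= 0)
    stop_invalid("`cell_size` must be a single positive number (metres)")
  if (length(origin) != 2 || !all(is.finite(origin)))
    stop_invalid("`origin` must be (x, y) in metres")
  structure(
    list(values = unname(values), cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), gsd = as.numeric(gsd)),
    class = "elev_raster"
  )
}

#' @export
print.elev_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<elev_raster> %d x %d cells @ %g m (%.2f x %.2f m)\n",
              nrow(v), ncol(v), x$cell_size,
              ncol(v) * x$cell_size, nrow(v) * x$cell_size))
  cat(sprintf("  valid cells: %d / %d; elevation range [%g, %g] m\n",
              sum(!is.na(v)), length(v),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' Benthic category mask
#'
#' A categorical grid labelling each cell `Live`, `Dead` or `Other` (stored as
#' integer codes 1, 2, 3; `NA` is no-data), aligned cell-for-cell with an
#' [elev_raster()]. `Live` is coral structure with living tissue, `Dead` is
#' coral skeleton without living tissue, and `Other` is any non-coral
#' substrate (predominantly sand in shallow reef surveys).
#'
#' @param labels integer matrix over codes 1 (Live), 2 (Dead), 3 (Other); `NA`
#'   marks no-data. Character matrices over the category names are accepted.
#' @param cell_size cell edge length in metres.
#' @param origin `(x, y)` of the lower-left corner in metres.
#' @return An object of class `benthic_mask`.
#' @export
benthic_mask <- function(labels, cell_size, origin = c(0, 0)) {
  if (is.character(labels)) {
    m <- match(labels, benthic_categories())
    if (any(is.na(m) & !is.na(labels)))
      stop_invalid("labels must be in Live/Dead/Other")
    labels <- matrix(m, nrow(labels), ncol(labels))
  }
  if (!is.matrix(labels) || !(is.numeric(labels) || is.integer(labels)))
    stop_invalid("`labels` must be an integer matrix")
  bad <- !is.na(labels) & !(labels %in% 1:3)
  if (any(bad)) stop_invalid("mask codes must be 1 (Live), 2 (Dead), 3 (Other) or NA")
  if (!is.numeric(cell_size) || cell_size <= 0)
    stop_invalid("`cell_size` must be positive")
  structure(
    list(labels = matrix(as.integer(labels), nrow(labels), ncol(labels)),
         cell_size = as.numeric(cell_size), origin = as.numeric(origin)),
    class = "benthic_mask"
  )
}

#' @export
print.benthic_mask <- function(x, ...) {
  tab <- tabulate(x$labels[!is.na(x$labels)], 3)
  cat(sprintf("<benthic_mask> %d x %d cells @ %g m\n",
              nrow(x$labels), ncol(x$labels), x$cell_size))
  cat(sprintf("  Live %d | Dead %d | Other %d | no-data %d\n",
              tab[1], tab[2], tab[3], sum(is.na(x$labels))))
  invisible(x)
}

#' Benthic category names, in fixed order
#'
#' The fixed category order (Live, Dead, Other) used by mask codes,
#' composition records and pivot log-ratio coordinates.
#' @return Character vector of length 3.
#' @export
benthic_categories <- function() c("Live", "Dead", "Other")

same_grid <- function(a, b, tol = 1e-9) {
  da <- if (inherits(a, "elev_raster")) dim(a$values) else dim(a$labels)
  db <- if (inherits(b, "elev_raster")) dim(b$values) else dim(b$labels)
  identical(da, db) &&
    abs(a$cell_size - b$cell_size) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

check_aligned <- function(raster, mask) {
  if (!same_grid(raster, mask)) {
    da <- dim(raster$values); db <- dim(mask$labels)
    stop_misaligned(sprintf(
      "raster (%dx%d @ %g m, origin %g,%g) and mask (%dx%d @ %g m, origin %g,%g) are not aligned",
      da[1], da[2], raster$cell_size, raster$origin[1], raster$origin[2],
      db[1], db[2], mask$cell_size, mask$origin[1], mask$origin[2]))
  }
  invisible(TRUE)
}
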