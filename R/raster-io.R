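#' Read a DEM from an ESRI ASCII grid
#'
#' Reads a square-celled elevation raster from the ESRI ASCII grid (`.asc`)
#' interchange format. Cells equal to the file's `NODATA_value` are marked
#' no-data and excluded from every metric. Files declaring rectangular cells
#' (`dx`/`dy` headers with `dx != dy`) are rejected: all terrain metrics here
#' assume square cells.
#'
#' @param path path to an `.asc` file.
#' @param gsd optional native ground sampling distance (m/pixel) to attach as
#'   provenance; defaults to the file's cell size.
#' @return An [elev_raster()].
#' @export
read_dem <- function(path, gsd = NULL) {
  hdr <- read_ascii_grid(path)
  elev_raster(hdr$values, cell_size = hdr$cell_size, origin = hdr$origin,
              gsd = if (is.null(gsd)) hdr$cell_size else gsd)
}

#' Write a DEM to an ESRI ASCII grid
#'
#' `read_dem(write_dem(r, path))` is the identity up to the decimal precision
#' of the text representation (15 significant digits).
#'
#' @param raster an [elev_raster()].
#' @param path output path; the extension must be `.asc`.
#' @param nodata sentinel written for no-data cells.
#' @return `path`, invisibly usable in pipes.
#' @export
write_dem <- function(raster, path, nodata = -9999) {
  stopifnot(inherits(raster, "elev_raster"))
  write_ascii_grid(raster$values, raster$cell_size, raster$origin, path, nodata,
                   digits = 15)
  path
}

#' Read or write a benthic mask as an ESRI ASCII grid
#'
#' Masks travel as integer ASCII grids with codes 1 = Live, 2 = Dead,
#' 3 = Other and 0 = no-data.
#'
#' @param path path to an `.asc` file.
#' @return `read_mask()` returns a [benthic_mask()]; `write_mask()` returns
#'   `path`.
#' @export
read_mask <- function(path) {
  hdr <- read_ascii_grid(path, nodata_extra = 0)
  benthic_mask(hdr$values, cell_size = hdr$cell_size, origin = hdr$origin)
}

#' @rdname read_mask
#' @param mask a [benthic_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "benthic_mask"))
  v <- mask$labels
  v[is.na(v)] <- 0L
  write_ascii_grid(v, mask$cell_size, mask$origin, path, nodata = 0, digits = 1)
  path
}

read_ascii_grid <- function(path, nodata_extra = NULL) {
  if (!is.character(path) || length(path) != 1)
    stop_invalid("`path` must be a single file path")
  if (!file.exists(path)) stop_not_found(paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("asc", "agr", "txt"))
    stop_unsupported(sprintf(
      "unsupported raster format '.%s': this build reads ESRI ASCII grids (.asc)", ext))
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  req <- c("ncols", "nrows")
  if (!all(req %in% names(hdr))) stop_malformed("missing ncols/nrows header")
  if (!is.null(hdr$dx) || !is.null(hdr$dy)) {
    if (is.null(hdr$dx) || is.null(hdr$dy) || abs(hdr$dx - hdr$dy) > 1e-12)
      stop_unsupported("rectangular (non-square) cells are not supported")
    cell <- hdr$dx
  } else if (!is.null(hdr$cellsize)) {
    cell <- hdr$cellsize
  } else stop_malformed("missing cellsize header")
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop_malformed(sprintf("expected %d values, found %d", nr * nc, length(vals)))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE) # first row = north
  nodata <- c(hdr$nodata_value, nodata_extra)
  for (nd in nodata) m[m == nd] <- NA
  ox <- hdr$xllcorner; oy <- hdr$yllcorner
  if (is.null(ox)) ox <- if (!is.null(hdr$xllcenter)) hdr$xllcenter - cell / 2 else 0
  if (is.null(oy)) oy <- if (!is.null(hdr$yllcenter)) hdr$yllcenter - cell / 2 else 0
  list(values = m, cell_size = cell, origin = c(ox, oy))
}

write_ascii_grid <- function(values, cell_size, origin, path, nodata, digits) {
  ext <- tolower(tools::file_ext(path))
  if (ext != "asc")
    stop_unsupported(sprintf(
      "unsupported output format '.%s': this build writes ESRI ASCII grids (.asc)", ext))
  if (!dir.exists(dirname(path)))
    abort_reef("io", paste0("parent directory does not exist: ", dirname(path)))
  v <- values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(values)),
    sprintf("nrows %d", nrow(values)),
    sprintf("xllcorner %.10g", origin[1]),
    sprintf("yllcorner %.10g", origin[2]),
    sprintf("cellsize %.15g", cell_size),
    sprintf("NODATA_value %g", nodata)
  ), con)
  writeLines(apply(v, 1, function(row)
    paste(formatC(row, format = "g", digits = digits), collapse = " ")), con)
  invisible(path)
}

#' Rasterize GeoJSON benthic polygons onto a raster grid
#'
#' Converts a GeoJSON `FeatureCollection` of polygons, each carrying a
#' `category` property in `Live`/`Dead`/`Other`, to a [benthic_mask()] on the
#' grid of `template`. Membership is decided by the cell centre (even-odd
#' rule); a cell covered by several polygons takes the category of the
#' polygon listed first, mirroring the precedence of manual digitization
#' order. Cells covered by no polygon are no-data.
#'
#' @param path path to a GeoJSON file.
#' @param template an [elev_raster()] supplying the target grid geometry.
#' @return A [benthic_mask()] aligned with `template`.
#' @export
mask_from_geojson <- function(path, template) {
  if (!file.exists(path)) stop_not_found(paste0("file not found: ", path))
  stopifnot(inherits(template, "elev_raster"))
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  if (is.null(feats) || length(feats) == 0)
    stop_malformed("GeoJSON has no features")
  nr <- nrow(template$values); nc <- ncol(template$values)
  cs <- template$cell_size
  cx <- template$origin[1] + (rep(seq_len(nc), each = nr) - 0.5) * cs
  cy <- template$origin[2] + (nr - rep(seq_len(nr), times = nc) + 0.5) * cs
  lab <- rep(NA_integer_, nr * nc)
  for (ft in feats) {
    cat_name <- ft$properties$category
    code <- match(cat_name, benthic_categories())
    if (is.na(code))
      stop_malformed(paste0("polygon category must be Live/Dead/Other, got: ",
                            as.character(cat_name)))
    geom <- ft$geometry
    rings <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop_unsupported(paste0("unsupported geometry type: ", geom$type)))
    todo <- which(is.na(lab))
    if (length(todo) == 0) break
    inside <- rep(FALSE, length(todo))
    for (poly in rings) {
      for (ring in poly) {
        xs <- vapply(ring, function(p) as.numeric(p[[1]]), 0)
        ys <- vapply(ring, function(p) as.numeric(p[[2]]), 0)
        inside <- xor(inside, point_in_ring(cx[todo], cy[todo], xs, ys))
      }
    }
    lab[todo[inside]] <- code
  }
  benthic_mask(matrix(lab, nr, nc), cell_size = cs, origin = template$origin)
}

# even-odd ray casting, vectorized over query points
point_in_ring <- function(px, py, xs, ys) {
  n <- length(xs)
  if (n > 1 && xs[1] == xs[n] && ys[1] == ys[n]) n <- n - 1
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Aggregate a raster to a coarser working grid by block means
#'
#' Block-mean aggregation: each `target_cell / cell_size` square block of
#' cells becomes one output cell holding the block mean. A block containing
#' any no-data cell becomes no-data (conservative). Trailing rows/columns
#' that do not fill a complete block are dropped. Block means preserve
#' integrated elevation, which is what area-based structural metrics need;
#' native photogrammetric grids (~0.0006 m GSD) are brought to the 0.01 m
#' working grid this way before any metric is computed.
#'
#' @param raster an [elev_raster()].
#' @param target_cell output cell size in metres; must be an integer multiple
#'   of `raster$cell_size` (to 1e-9) and at least as large.
#' @return An [elev_raster()] with `cell_size = target_cell`.
#' @export
resample_to_grid <- function(raster, target_cell) {
  stopifnot(inherits(raster, "elev_raster"))
  cs <- raster$cell_size
  if (target_cell < cs - 1e-12)
    stop_invalid("`target_cell` must be >= the raster cell size")
  f <- target_cell / cs
  if (abs(f - round(f)) > 1e-9)
    stop_invalid(sprintf(
      "`target_cell` (%g) is not an integer multiple of the cell size (%g)",
      target_cell, cs))
  f <- as.integer(round(f))
  if (f == 1L) {
    out <- raster; out$cell_size <- target_cell
    return(out)
  }
  out_vals <- block_reduce_mean(raster$values, f)
  # partial blocks are dropped at the matrix bottom/right, i.e. the south
  # and east edges, so the lower-left origin moves north by the dropped rows
  nr_dropped <- nrow(raster$values) - nrow(out_vals) * f
  elev_raster(out_vals, cell_size = target_cell,
              origin = c(raster$origin[1],
                         raster$origin[2] + nr_dropped * cs),
              gsd = raster$gsd)
}

block_reduce_mean <- function(m, f) {
  nr <- nrow(m) %/% f
  nc <- ncol(m) %/% f
  if (nr < 1 || nc < 1) stop_invalid("aggregation factor exceeds grid size")
  mm <- m[seq_len(nr * f), seq_len(nc * f), drop = FALSE]
  a <- array(mm, dim = c(f, nr, f, nc))
  colMeans(aperm(a, c(1, 3, 2, 4)), dims = 2) # NA-propagating block mean
}

#' Trim raster edges by aggregation-factor blocks
#'
#' The edge-trimming procedure used to give every colony a consistent,
#' block-aligned analysis footprint: the grid is divided into
#' `factor` x `factor` blocks anchored at the top-left cell; any block that
#' contains a no-data cell (i.e. reaches outside the model boundary) or is an
#' incomplete edge block is nulled, and the original-resolution raster is
#' clipped to the union of the surviving blocks. Grid dimensions are
#' unchanged; only the valid-cell set shrinks. The operation is idempotent at
#' a fixed factor, never adds valid cells, and the valid-cell count is
#' non-increasing in `factor`.
#'
#' @param raster an [elev_raster()].
#' @param factor positive integer block edge, in cells.
#' @return An [elev_raster()] with the same grid and a (possibly) reduced
#'   valid-cell set.
#' @export
aggregate_clip <- function(raster, factor) {
  stopifnot(inherits(raster, "elev_raster"))
  if (!is_count(factor)) stop_invalid("`factor` must be a positive integer")
  factor <- as.integer(round(factor))
  v <- raster$values
  if (factor > nrow(v) || factor > ncol(v))
    stop_invalid(sprintf("factor %d exceeds grid dimensions %dx%d",
                         factor, nrow(v), ncol(v)))
  if (factor == 1L) return(raster)
  nbr <- nrow(v) %/% factor
  nbc <- ncol(v) %/% factor
  keep <- matrix(FALSE, nrow(v), ncol(v))
  ri <- seq_len(nbr * factor)
  ci <- seq_len(nbc * factor)
  ok <- block_reduce_all_valid(!is.na(v[ri, ci, drop = FALSE]), factor)
  keep[ri, ci] <- ok[rep(seq_len(nbr), each = factor),
                     rep(seq_len(nbc), each = factor)]
  v[!keep] <- NA
  out <- raster
  out$values <- v
  out
}

block_reduce_all_valid <- function(valid, f) {
  nr <- nrow(valid) %/% f
  nc <- ncol(valid) %/% f
  a <- array(valid[seq_len(nr * f), seq_len(nc * f), drop = FALSE],
             dim = c(f, nr, f, nc))
  colSums(aperm(a, c(1, 3, 2, 4)), dims = 2) == f * f
}

#' Quantify benthic composition from a categorical mask
#'
#' Area of a category = (number of cells labelled with it) x cell area, the
#' raster re-implementation of polygon area measurement on an orthomosaic.
#' Categories absent from the mask get area 0 -- a rounded zero, to be
#' replaced downstream before any log-ratio transformation (see
#' [replace_rounded_zeros()]). The detection limit is the area of one native
#' pixel, GSD squared.
#'
#' @param mask a [benthic_mask()].
#' @param colony_id identifier copied into the record.
#' @param detection_limit_area detection limit in m^2 (one native pixel).
#' @return A one-row tibble: `colony_id`, `live_m2`, `dead_m2`, `other_m2`,
#'   `total_m2`, `detection_limit_m2`. `total_m2` equals valid-cell count
#'   times cell area exactly.
#' @export
quantify_areas <- function(mask, colony_id = "colony",
                           detection_limit_area = mask$cell_size^2) {
  stopifnot(inherits(mask, "benthic_mask"))
  lab <- mask$labels[!is.na(mask$labels)]
  if (length(lab) == 0) stop_empty("mask has no valid cells")
  if (!is.numeric(detection_limit_area) || detection_limit_area <= 0)
    stop_invalid("`detection_limit_area` must be positive")
  counts <- tabulate(lab, nbins = 3)
  ca <- mask$cell_size^2
  tibble::tibble(
    colony_id = as.character(colony_id),
    live_m2  = counts[1] * ca,
    dead_m2  = counts[2] * ca,
    other_m2 = counts[3] * ca,
    total_m2 = length(lab) * ca,
    detection_limit_m2 = detection_limit_area
  )
}
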