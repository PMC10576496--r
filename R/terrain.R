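#' Planform (map-projected) surface area
#'
#' Valid-cell count times cell area, in m^2. This is the 2-D footprint of the
#' model, the denominator of surface rugosity, and the quantity reported as
#' planform surface area in colony summary tables.
#'
#' @param raster an [elev_raster()].
#' @return Area in m^2.
#' @export
planform_area <- function(raster) {
  stopifnot(inherits(raster, "elev_raster"))
  n <- sum(!is.na(raster$values))
  if (n == 0) stop_empty("raster has no valid cells")
  n * raster$cell_size^2
}

#' 3-D geodesic surface area
#'
#' Triangulates the elevation lattice (cell centres as nodes): every 2x2
#' block of valid nodes contributes two 3-D triangles split along the NW-SE
#' diagonal, and the summed triangle area is scaled by the ratio of valid
#' cells to complete valid blocks. The scaling is an edge correction: the
#' triangle mesh spans only the inter-node blocks, so boundary half-cells
#' would otherwise be omitted and a flat raster would not return its exact
#' planform area. With it, a horizontal plane returns the planform area to
#' machine precision and a plane at angle `theta` returns
#' `planform / cos(theta)` exactly, so rugosity anchors are exact.
#'
#' @param raster an [elev_raster()].
#' @return Area in m^2; always at least the planform area.
#' @export
geodesic_area <- function(raster) {
  stopifnot(inherits(raster, "elev_raster"))
  z <- raster$values
  cs <- raster$cell_size
  n_valid <- sum(!is.na(z))
  if (n_valid == 0) stop_empty("raster has no valid cells")
  nr <- nrow(z); nc <- ncol(z)
  z1 <- z[-nr, -nc]; z2 <- z[-nr, -1]   # NW, NE
  z3 <- z[-1, -nc];  z4 <- z[-1, -1]    # SW, SE
  # triangle (NW, NE, SE): cross product of (cs,0,z2-z1) and (cs,-cs,z4-z1)
  a1 <- 0.5 * sqrt((cs * (z2 - z4))^2 + (cs * (z2 - z1))^2 + (cs * cs)^2)
  # triangle (NW, SE, SW): cross product of (cs,-cs,z4-z1) and (0,-cs,z3-z1)
  a2 <- 0.5 * sqrt((cs * (z3 - z4))^2 + (cs * (z3 - z1))^2 + (cs * cs)^2)
  ok <- !is.na(a1) & !is.na(a2)
  nq <- sum(ok)
  if (nq == 0)
    stop_degenerate("fewer than one complete 2x2 valid block; surface is degenerate")
  (sum(a1[ok]) + sum(a2[ok])) * n_valid / nq
}

#' Surface rugosity
#'
#' Ratio of 3-D geodesic surface area to planform area over the same valid
#' footprint. Dimensionless, at least 1, with equality exactly when the
#' surface is flat. (At colony extents of a few m^2 the distinction between a
#' planar and an ellipsoidal reference surface is far below numerical
#' precision, so the planform footprint is the reference.)
#'
#' @param raster an [elev_raster()].
#' @return Rugosity (dimensionless, >= 1).
#' @export
surface_rugosity <- function(raster) {
  geodesic_area(raster) / planform_area(raster)
}

#' Multiscale surface-area curve
#'
#' Computes the geodesic surface area `S(delta)` of a raster at a ladder of
#' working resolutions: for each aggregation factor the raster is
#' edge-trimmed with [aggregate_clip()], block-mean resampled to
#' `delta = factor * cell_size`, and triangulated with [geodesic_area()].
#' The least-squares slope and R^2 of `log S` against `log delta` (natural
#' logs) summarize how detail decays with resolution; `2 - slope` is the
#' fractal dimension (see [fractal_dimension()]).
#'
#' Factors whose clipped raster has no complete valid block are dropped with
#' a warning. For consistent multiscale footprints, trim the raster once at
#' the coarsest factor first (as [colony_metrics()] does).
#'
#' @param raster an [elev_raster()] already on the working grid (nominally
#'   0.01 m cells).
#' @param factors increasing positive integer aggregation factors; the
#'   default 1, 2, 4, 8, 16, 32 spans working cell sizes of 1-32 cm. The
#'   coarsest `factor * cell_size` must not exceed a quarter of the shorter
#'   grid extent.
#' @return A `surface_area_curve`: tibble of (`resolution_m`, `area_m2`) with
#'   attributes `log_slope` and `r_squared`.
#' @export
surface_area_curve <- function(raster, factors = c(1, 2, 4, 8, 16, 32)) {
  stopifnot(inherits(raster, "elev_raster"))
  if (length(factors) < 3 || any(!vapply(factors, is_count, TRUE)))
    stop_invalid("`factors` must be >= 3 positive integers")
  factors <- sort(as.integer(round(factors)))
  ext <- min(dim(raster$values)) * raster$cell_size
  worst <- max(factors)
  if (worst * raster$cell_size > ext / 4 + 1e-12)
    stop_invalid(sprintf(
      "factor %d gives a step of %g m, exceeding a quarter of the %g m grid extent",
      worst, worst * raster$cell_size, ext))
  areas <- vapply(factors, function(f) {
    rc <- aggregate_clip(raster, f)
    rr <- resample_to_grid(rc, f * raster$cell_size)
    tryCatch(geodesic_area(rr), reefmorph_error = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(areas)) {
    warn(sprintf("dropping %d factor(s) with no complete valid block: %s",
                 sum(is.na(areas)),
                 paste(factors[is.na(areas)], collapse = ", ")))
    factors <- factors[!is.na(areas)]
    areas <- areas[!is.na(areas)]
  }
  sa_curve(factors * raster$cell_size, areas)
}

#' Build a surface-area curve from (resolution, area) pairs
#'
#' Low-level constructor used by [surface_area_curve()] and directly useful
#' for testing the log-log fit against analytically injected curves.
#'
#' @param resolutions strictly increasing resolutions `delta` (metres).
#' @param areas geodesic areas `S(delta)` (m^2, positive).
#' @return A `surface_area_curve` object.
#' @export
sa_curve <- function(resolutions, areas) {
  if (length(resolutions) != length(areas) || length(resolutions) < 3)
    stop_invalid("need >= 3 (resolution, area) pairs")
  if (any(diff(resolutions) <= 0))
    stop_invalid("`resolutions` must be strictly increasing")
  if (any(!is.finite(areas)) || any(areas <= 0))
    stop_invalid("`areas` must be strictly positive")
  if (any(diff(log(areas)) > 1e-9))
    warn("S(delta) increases with delta at some steps; fractality is doubtful")
  x <- log(resolutions); y <- log(areas)
  fit <- lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  # a zero-variance (flat-surface) curve is a perfect linear fit
  r2 <- if (ss_tot < 1e-24) 1 else 1 - ss_res / ss_tot
  out <- tibble::tibble(resolution_m = as.numeric(resolutions),
                        area_m2 = as.numeric(areas))
  attr(out, "log_slope") <- unname(coef(fit)[2])
  attr(out, "r_squared") <- r2
  class(out) <- c("surface_area_curve", class(out))
  out
}

#' Fractal dimension from a surface-area curve
#'
#' `D = 2 - slope[log S(delta) / log delta]`: the area-based multiscale
#' complexity index for surfaces, ranging from 2 (flat) to 3. The linearity
#' of the log-log relationship -- fractality over the tested step range -- is
#' a prerequisite for a meaningful `D`; the visual check of practice is made
#' objective here as `is_fractal = (R^2 >= linearity_threshold)`. `d` is
#' reported regardless, with the flag signalling unreliable fractality.
#'
#' @param curve a `surface_area_curve` (from [surface_area_curve()] or
#'   [sa_curve()]).
#' @param linearity_threshold minimum R^2 of the log-log fit.
#' @return A `fractal_fit` list: `d`, `r_squared`, `is_fractal`,
#'   `step_range` (metres).
#' @export
fractal_dimension <- function(curve, linearity_threshold = 0.98) {
  if (!inherits(curve, "surface_area_curve"))
    stop_invalid("`curve` must be a surface_area_curve")
  structure(list(
    d = 2 - attr(curve, "log_slope"),
    r_squared = attr(curve, "r_squared"),
    is_fractal = attr(curve, "r_squared") >= linearity_threshold,
    step_range = range(curve$resolution_m)), class = "fractal_fit")
}

#' @export
print.fractal_fit <- function(x, ...) {
  cat(sprintf("<fractal_fit> D = %.4f (R^2 = %.4f, %sfractal over %g-%g m)\n",
              x$d, x$r_squared, if (x$is_fractal) "" else "NOT ",
              x$step_range[1], x$step_range[2]))
  invisible(x)
}

# Zevenbergen-Thorne 3x3 window coefficients on shifted submatrices.
# Matrix row 1 is north. Returns interior-sized matrices (border trimmed).
zt_coefficients <- function(z, cs, method = c("zevenbergen_thorne", "evans")) {
  method <- match.arg(method)
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) stop_empty_result("need at least a 3x3 grid")
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  z1 <- z[i - 1, j - 1]; z2 <- z[i - 1, j]; z3 <- z[i - 1, j + 1]
  z4 <- z[i, j - 1];     z5 <- z[i, j];     z6 <- z[i, j + 1]
  z7 <- z[i + 1, j - 1]; z8 <- z[i + 1, j]; z9 <- z[i + 1, j + 1]
  if (method == "zevenbergen_thorne") {
    D <- ((z4 + z6) / 2 - z5) / cs^2
    E <- ((z2 + z8) / 2 - z5) / cs^2
    F <- (-z1 + z3 + z7 - z9) / (4 * cs^2)
    G <- (-z4 + z6) / (2 * cs)
    H <- (z2 - z8) / (2 * cs)
  } else {
    # Evans: least-squares quadratic over all 9 nodes
    D <- (z1 + z3 + z4 + z6 + z7 + z9 - 2 * (z2 + z5 + z8)) / (6 * cs^2)
    E <- (z1 + z2 + z3 + z7 + z8 + z9 - 2 * (z4 + z5 + z6)) / (6 * cs^2)
    F <- (-z1 + z3 + z7 - z9) / (4 * cs^2)
    G <- (-z1 + z3 - z4 + z6 - z7 + z9) / (6 * cs)
    H <- (z1 + z2 + z3 - z7 - z8 - z9) / (6 * cs)
  }
  list(D = D, E = E, F = F, G = G, H = H)
}

pad_border_na <- function(interior, nr, nc) {
  out <- matrix(NA_real_, nr, nc)
  out[2:(nr - 1), 2:(nc - 1)] <- interior
  out
}

#' Per-cell slope in degrees
#'
#' Slope from the Zevenbergen-Thorne surface fitted to each interior cell's
#' 3x3 window: `atan(sqrt(G^2 + H^2))` in degrees, where `G` and `H` are the
#' east-west and north-south first-order gradients over `2 * cell_size`.
#' Border cells and cells whose window contains no-data are no-data.
#'
#' @param raster an [elev_raster()].
#' @param method `"zevenbergen_thorne"` (default) or `"evans"` (full
#'   least-squares quadratic).
#' @return Matrix of slopes in degrees, same shape as the raster.
#' @export
slope_cells <- function(raster, method = "zevenbergen_thorne") {
  stopifnot(inherits(raster, "elev_raster"))
  z <- raster$values
  co <- zt_coefficients(z, raster$cell_size, method)
  sl <- atan(sqrt(co$G^2 + co$H^2)) * 180 / pi
  out <- pad_border_na(sl, nrow(z), ncol(z))
  if (all(is.na(out))) stop_empty_result("no interior cell has a complete 3x3 window")
  out
}

#' Per-cell planform and profile curvature
#'
#' Curvatures from the same 3x3 window surface fit, scaled by 100 (the
#' conventional reporting scale for terrain curvature):
#' profile `= -2 (D G^2 + E H^2 + F G H) / (G^2 + H^2) * 100` (rate of change
#' of slope along the slope direction; positive = convex-upslope) and
#' planform `= 2 (D H^2 + E G^2 - F G H) / (G^2 + H^2) * 100` (curvature of
#' the surface perpendicular to the slope, i.e. contour curvature). Cells
#' with a vanishing gradient (`G^2 + H^2 < 1e-12`) are flat and take
#' curvature 0 by convention -- this keeps dispersion summaries defined on
#' near-planar sandy substrate.
#'
#' @param raster an [elev_raster()].
#' @param kind `"planform"` or `"profile"`.
#' @param method `"zevenbergen_thorne"` (default) or `"evans"`.
#' @return Matrix of curvatures, same shape as the raster.
#' @export
curvature_cells <- function(raster, kind = c("planform", "profile"),
                            method = "zevenbergen_thorne") {
  stopifnot(inherits(raster, "elev_raster"))
  kind <- match.arg(kind)
  z <- raster$values
  co <- zt_coefficients(z, raster$cell_size, method)
  g2 <- co$G^2 + co$H^2
  curv <- if (kind == "profile") {
    -2 * (co$D * co$G^2 + co$E * co$H^2 + co$F * co$G * co$H) / g2 * 100
  } else {
    2 * (co$D * co$H^2 + co$E * co$G^2 - co$F * co$G * co$H) / g2 * 100
  }
  curv[!is.na(g2) & g2 < 1e-12] <- 0
  out <- pad_border_na(curv, nrow(z), ncol(z))
  if (all(is.na(out))) stop_empty_result("no interior cell has a complete 3x3 window")
  out
}

#' Summary statistics of a per-cell metric grid
#'
#' Mean, median, minimum, maximum, lower and upper quartile, and
#' interquartile range over valid cells. Quartiles use the linear
#' interpolation convention (R's default quantile type 7), fixed so IQRs are
#' reproducible. The IQR is the preferred dispersion summary at colony
#' scale, where means oversimplify highly variable structure.
#'
#' @param grid numeric matrix or vector of per-cell metric values (`NA`
#'   ignored).
#' @return One-row tibble: `mean`, `median`, `min`, `max`, `q1`, `q3`, `iqr`.
#' @export
summarize_cells <- function(grid) {
  v <- as.numeric(grid)
  v <- v[is.finite(v)]
  if (length(v) == 0) stop_empty("no valid values to summarize")
  q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(mean = mean(v), median = q[2], min = min(v), max = max(v),
                 q1 = q[1], q3 = q[3], iqr = q[3] - q[1])
}

#' Full structural-metric battery for one colony
#'
#' Runs the five structural metrics on a DEM: surface rugosity, fractal
#' dimension from the multiscale surface-area curve, and summary statistics
#' of per-cell slope, planform curvature and profile curvature. The raster
#' is first edge-trimmed at the coarsest aggregation factor
#' ([aggregate_clip()]) so that every resolution of the `S(delta)` ladder
#' sees the identical block-aligned footprint -- without this the footprint
#' would shrink at coarse steps and bias the log-log slope.
#'
#' With a mask and `category`, metrics are computed on the raster restricted
#' to that category's cells. A restricted region too small to triangulate
#' (less than one complete 2x2 block) or with fewer than 3 usable curve
#' points reports its surface metrics as `NA` with a warning.
#'
#' @param raster an [elev_raster()] on the working grid.
#' @param mask optional aligned [benthic_mask()].
#' @param category optional category name (`"Live"`, `"Dead"`, `"Other"`) to
#'   restrict to; requires `mask`.
#' @param config a [study_config()]; supplies factors, linearity threshold
#'   and curvature method.
#' @param colony_id identifier copied into the output row.
#' @return A one-row tibble: identifiers, `planform_area_m2`,
#'   `geodesic_area_m2`, `surface_rugosity`, `fractal_d`, `fractal_r2`,
#'   `is_fractal`, and `slope_`/`plan_curv_`/`prof_curv_` summary columns
#'   (`*_mean`, `*_median`, `*_min`, `*_max`, `*_q1`, `*_q3`, `*_iqr`).
#' @export
colony_metrics <- function(raster, mask = NULL, category = NULL,
                           config = study_config(), colony_id = "colony") {
  stopifnot(inherits(raster, "elev_raster"))
  if (!is.null(category)) {
    if (is.null(mask)) stop_invalid("`category` requires a mask")
    code <- match(match.arg(category, benthic_categories()),
                  benthic_categories())
    check_aligned(raster, mask)
    v <- raster$values
    v[is.na(mask$labels) | mask$labels != code] <- NA
    raster <- elev_raster(v, raster$cell_size, raster$origin, raster$gsd)
  } else if (!is.null(mask)) {
    check_aligned(raster, mask)
  }
  factors <- config$factors
  # whole-colony runs get the one-time edge trim at the coarsest factor so
  # every resolution sees the same footprint; category-restricted regions
  # are blob-shaped and rarely contain complete coarsest blocks, so they
  # rely on the per-factor clip inside surface_area_curve instead
  trimmed <- if (is.null(category)) aggregate_clip(raster, max(factors)) else raster
  empty_stats <- function() tibble::tibble(mean = NA_real_, median = NA_real_,
                                           min = NA_real_, max = NA_real_,
                                           q1 = NA_real_, q3 = NA_real_,
                                           iqr = NA_real_)
  pa <- tryCatch(planform_area(trimmed), reefmorph_error = function(e) NA_real_)
  ga <- tryCatch(geodesic_area(trimmed), reefmorph_error = function(e) NA_real_)
  ff <- list(d = NA_real_, r_squared = NA_real_, is_fractal = NA)
  if (!is.na(ga)) {
    curve <- withCallingHandlers(
      tryCatch(surface_area_curve(trimmed, factors),
               reefmorph_error = function(e) NULL),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!is.null(curve) && nrow(curve) >= 3) {
      ff <- fractal_dimension(curve, config$linearity_threshold)
    } else {
      warn(sprintf("colony %s: too few usable resolutions; fractal dimension is NA",
                   colony_id))
    }
  } else {
    warn(sprintf(
      "colony %s: region smaller than one 2x2 block; surface metrics are NA",
      colony_id))
  }
  sl <- tryCatch(
    summarize_cells(slope_cells(trimmed, config$curvature_method)),
    reefmorph_error = function(e) empty_stats())
  pc <- tryCatch(
    summarize_cells(curvature_cells(trimmed, "planform", config$curvature_method)),
    reefmorph_error = function(e) empty_stats())
  fc <- tryCatch(
    summarize_cells(curvature_cells(trimmed, "profile", config$curvature_method)),
    reefmorph_error = function(e) empty_stats())
  pre <- function(df, p) stats::setNames(df, paste0(p, names(df)))
  dplyr::bind_cols(
    tibble::tibble(colony_id = as.character(colony_id),
                   category = if (is.null(category)) "All" else category,
                   planform_area_m2 = pa, geodesic_area_m2 = ga,
                   surface_rugosity = ga / pa,
                   fractal_d = ff$d, fractal_r2 = ff$r_squared,
                   is_fractal = ff$is_fractal),
    pre(sl, "slope_"), pre(pc, "plan_curv_"), pre(fc, "prof_curv_")
  )
}
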