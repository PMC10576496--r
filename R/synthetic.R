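#' Simulate a fractional Brownian surface DEM
#'
#' Synthesizes a self-affine random surface spectrally: white Gaussian noise
#' is filtered in the frequency domain so the power spectral density falls as
#' `f^-(2*hurst + 2)`, which gives a surface of theoretical fractal dimension
#' `3 - hurst`. The field is rescaled so its elevation standard deviation
#' equals `amplitude` exactly (so doubling `amplitude` doubles the SD
#' bit-for-bit). Deterministic for a fixed seed; the generator uses its own
#' seeded stream and leaves the caller's RNG state untouched.
#'
#' Spectral synthesis (rather than midpoint displacement) gives exact control
#' of the power-law exponent and costs a single FFT on a 256^2 grid.
#'
#' @param hurst Hurst exponent, strictly inside (0, 1). Small values are
#'   rough (D near 3), large values smooth (D near 2).
#' @param grid_cells cells per side; a power of two, at least 64.
#' @param cell_size cell edge in metres.
#' @param amplitude target elevation standard deviation in metres (> 0).
#' @param seed integer seed.
#' @return An [elev_raster()] of `grid_cells` x `grid_cells` elevations.
#' @examples
#' dem <- gen_fbm_dem(hurst = 0.5, grid_cells = 64, cell_size = 0.01,
#'                    amplitude = 0.05, seed = 1)
#' @export
gen_fbm_dem <- function(hurst, grid_cells, cell_size = 0.01, amplitude = 0.05,
                        seed = 1) {
  if (!is.numeric(hurst) || length(hurst) != 1 || !is.finite(hurst) ||
      hurst <= 0 || hurst >= 1)
    stop_invalid("`hurst` must lie strictly inside (0, 1)")
  if (!is_count(grid_cells) || grid_cells < 64 || !is_power_of_two(grid_cells))
    stop_invalid("`grid_cells` must be a power of two >= 64")
  if (!is.numeric(amplitude) || length(amplitude) != 1 || !is.finite(amplitude) ||
      amplitude <= 0)
    stop_invalid("`amplitude` must be positive")
  n <- as.integer(grid_cells)
  w_hat <- withr::with_seed(seed_stream(seed, 1L),
                            stats::fft(matrix(rnorm(n * n), n, n)))
  elev_raster(fbm_filter(w_hat, hurst, amplitude), cell_size = cell_size)
}

# filter a white-noise spectrum to PSD ~ f^-(2H+2) and rescale to `amplitude`
# elevation SD; sharing `w_hat` across Hurst exponents yields surfaces with
# identical phases that differ only in fine-scale roughness
fbm_filter <- function(w_hat, hurst, amplitude) {
  n <- nrow(w_hat)
  k <- 0:(n - 1)
  f1 <- pmin(k, n - k) / n                       # cycles per cell
  fr <- sqrt(outer(f1^2, f1^2, "+"))
  amp_spec <- fr^(-(hurst + 1))                  # PSD ~ f^-(2H+2)
  amp_spec[1, 1] <- 0                            # zero-mean surface
  z <- Re(stats::fft(w_hat * amp_spec, inverse = TRUE)) / (n * n)
  s <- sd(z)
  if (s == 0) stop_invalid("degenerate zero-variance field; cannot rescale")
  z * (amplitude / s)
}

#' Simulate a three-category benthic mask
#'
#' Builds a `Live`/`Dead`/`Other` mask by double-thresholding a smoothed
#' seeded Gaussian noise field: cells are ranked by the smoothed field and
#' assigned to categories in order, so realized category fractions match the
#' request to within one cell. Smoothing (a Gaussian kernel of scale
#' `smoothness` cells, applied spectrally) makes the categories contiguous
#' blobs rather than salt-and-pepper.
#'
#' @param grid_cells cells per side.
#' @param fractions length-3 proportions (Live, Dead, Other) summing to 1.
#' @param smoothness Gaussian smoothing length in cells (>= 1).
#' @param cell_size cell edge in metres.
#' @param seed integer seed.
#' @return A [benthic_mask()].
#' @export
gen_benthic_mask <- function(grid_cells, fractions, smoothness = 8,
                             cell_size = 0.01, seed = 1) {
  if (!is_count(grid_cells) || grid_cells < 8)
    stop_invalid("`grid_cells` must be a positive integer >= 8")
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop_invalid("`fractions` must be 3 non-negative proportions summing to 1")
  if (!is.numeric(smoothness) || smoothness < 1)
    stop_invalid("`smoothness` must be >= 1 cell")
  n <- as.integer(grid_cells)
  field <- withr::with_seed(seed_stream(seed, 2L), {
    w <- matrix(rnorm(n * n), n, n)
    k <- 0:(n - 1)
    f1 <- pmin(k, n - k) / n
    fr2 <- outer(f1^2, f1^2, "+")
    # patch diameter is a few multiples of `smoothness`; the 3x kernel scale
    # keeps categories in a handful of contiguous blobs on a 256^2 grid
    g <- exp(-2 * pi^2 * (3 * smoothness)^2 * fr2)
    Re(stats::fft(stats::fft(w) * g, inverse = TRUE)) / (n * n)
  })
  counts <- floor(fractions * n * n)
  rem <- n * n - sum(counts)
  if (rem > 0) { # give leftovers to the largest requested fractions
    ord <- order(fractions * n * n - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  lab <- integer(n * n)
  ord <- order(field)  # ties broken by index: deterministic
  lab[ord] <- rep.int(1:3, counts)
  benthic_mask(matrix(lab, n, n), cell_size = cell_size)
}

#' Colony simulation parameters
#'
#' Parameter bundle for [gen_colony()]. Defaults encode the study conditions
#' the generator emulates: Dead coral skeleton is rougher than Live tissue
#' (`hurst_dead < hurst_live`, larger amplitude), and Other substrate is
#' near-flat sand-scale texture. See the package vignette for the
#' calibration rationale.
#'
#' @param live_fraction,dead_fraction proportions in `[0, 1]` with
#'   `live_fraction + dead_fraction <= 1`; the remainder is Other.
#' @param hurst_live,hurst_dead Hurst exponents in (0, 1); the default
#'   ordering `hurst_dead < hurst_live` makes Dead the rougher category.
#' @param amplitude_live,amplitude_dead elevation SD of the two fBm fields
#'   (metres).
#' @param other_noise_sd SD of the Other-substrate texture around the base
#'   plane (metres).
#' @param grid_cells cells per side (need not be a power of two; the fBm
#'   fields are synthesized on the next power of two and cropped).
#' @param cell_size cell edge in metres.
#' @param mask_smoothness blob scale of the category mask, in cells.
#' @param seed integer seed.
#' @return A list of class `colony_params`.
#' @export
colony_params <- function(live_fraction = 0.35, dead_fraction = 0.5,
                          hurst_live = 0.8, hurst_dead = 0.45,
                          amplitude_live = 0.10, amplitude_dead = 0.18,
                          other_noise_sd = 0.002,
                          grid_cells = 160, cell_size = 0.01,
                          mask_smoothness = 8, seed = 1) {
  if (live_fraction < 0 || live_fraction > 1 ||
      dead_fraction < 0 || dead_fraction > 1 ||
      live_fraction + dead_fraction > 1 + 1e-12)
    stop_invalid("live_fraction + dead_fraction must lie in [0, 1]")
  for (h in c(hurst_live, hurst_dead))
    if (h <= 0 || h >= 1) stop_invalid("Hurst exponents must be in (0, 1)")
  if (amplitude_live <= 0 || amplitude_dead <= 0 || other_noise_sd < 0)
    stop_invalid("amplitudes must be positive")
  if (!is_count(grid_cells) || grid_cells < 64)
    stop_invalid("`grid_cells` must be an integer >= 64")
  structure(list(
    live_fraction = live_fraction, dead_fraction = dead_fraction,
    hurst_live = hurst_live, hurst_dead = hurst_dead,
    amplitude_live = amplitude_live, amplitude_dead = amplitude_dead,
    other_noise_sd = other_noise_sd, grid_cells = as.integer(grid_cells),
    cell_size = cell_size, mask_smoothness = mask_smoothness,
    seed = as.integer(seed)), class = "colony_params")
}

#' Simulate one coral colony: DEM plus benthic mask
#'
#' Composites category-specific surfaces through a simulated mask: Live cells
#' are drawn from the smoother fBm field, Dead cells from the rougher one,
#' and Other cells from low-amplitude Gaussian texture around the base plane.
#' The DEM and mask share grid geometry exactly. An optional `footprint`
#' restricts the colony to an irregular valid region (cells outside become
#' no-data in both layers), emulating the irregular survey boundaries of
#' field models.
#'
#' @param params a [colony_params()].
#' @param footprint optional logical matrix (`grid_cells` square): `TRUE`
#'   cells are inside the colony survey region.
#' @return A list with elements `dem` ([elev_raster()]), `mask`
#'   ([benthic_mask()]) and `params`.
#' @export
gen_colony <- function(params = colony_params(), footprint = NULL) {
  stopifnot(inherits(params, "colony_params"))
  p <- params
  n <- p$grid_cells
  n2 <- 2^ceiling(log2(max(n, 64)))
  crop <- function(z) z[seq_len(n), seq_len(n), drop = FALSE]
  # one white-noise spectrum drives both categories: Live is the smoother
  # rendering of the same underlying skeleton (identical phases, steeper
  # spectral decay), so category boundaries stay continuous at coarse
  # scales instead of introducing artificial cliffs
  w_hat <- withr::with_seed(seed_stream(p$seed, 11L),
                            stats::fft(matrix(rnorm(n2 * n2), n2, n2)))
  z_live <- crop(fbm_filter(w_hat, p$hurst_live, p$amplitude_live))
  z_dead <- crop(fbm_filter(w_hat, p$hurst_dead, p$amplitude_dead))
  z_other <- withr::with_seed(seed_stream(p$seed, 33L),
                              matrix(rnorm(n * n, sd = p$other_noise_sd), n, n))
  mask <- gen_benthic_mask(
    n, c(p$live_fraction, p$dead_fraction,
         1 - p$live_fraction - p$dead_fraction),
    smoothness = p$mask_smoothness, cell_size = p$cell_size,
    seed = seed_stream(p$seed, 44L))
  lab <- mask$labels
  z <- z_other
  z[lab == 1L] <- z_live[lab == 1L]
  z[lab == 2L] <- z_dead[lab == 2L]
  if (!is.null(footprint)) {
    if (!is.matrix(footprint) || !all(dim(footprint) == n))
      stop_invalid("`footprint` must be a logical matrix matching the grid")
    z[!footprint] <- NA
    lab[!footprint] <- NA
  }
  list(dem = elev_raster(z, cell_size = p$cell_size),
       mask = benthic_mask(lab, cell_size = p$cell_size),
       params = p)
}

#' Compositional regression simulation parameters
#'
#' Parameter bundle for [gen_coda_dataset()]. Compositions are drawn from a
#' Dirichlet whose default concentration (5, 5, 3) roughly matches the
#' relative category means of shallow *Acropora* colony surveys (Live and
#' Dead comparable, Other somewhat smaller); totals are uniform over
#' `total_area_range`.
#'
#' @param n_colonies number of colonies (>= 5).
#' @param coord_coefficients length-2 effects on the two pivot log-ratio
#'   coordinates.
#' @param intercept response intercept.
#' @param noise_sd Gaussian response noise SD (> 0).
#' @param outlier_fraction fraction of responses shifted, in `[0, 0.4]`.
#' @param outlier_shift additive shift applied to outlier responses.
#' @param total_area_range `(low, high)` total colony area range in m^2.
#' @param concentration Dirichlet concentration, length 3.
#' @param detection_limit_m2 detection limit recorded per colony (one native
#'   pixel; default 0.0006^2).
#' @param zero_prob probability that a colony's smallest part is floored to a
#'   recorded 0 (a rounded zero below the detection limit); 0 disables.
#' @param seed integer seed.
#' @return A list of class `coda_sim_params`.
#' @export
coda_sim_params <- function(n_colonies = 10, coord_coefficients = c(0.1, 0),
                            intercept = 2.36, noise_sd = 0.05,
                            outlier_fraction = 0, outlier_shift = 0,
                            total_area_range = c(1.2, 2.5),
                            concentration = c(5, 5, 3),
                            detection_limit_m2 = 3.6e-7,
                            zero_prob = 0, seed = 1) {
  if (!is_count(n_colonies) || n_colonies < 5)
    stop_invalid("`n_colonies` must be an integer >= 5 (regression degrees of freedom)")
  if (length(coord_coefficients) != 2)
    stop_invalid("`coord_coefficients` must have length 2")
  if (noise_sd <= 0) stop_invalid("`noise_sd` must be > 0")
  if (outlier_fraction < 0 || outlier_fraction > 0.4)
    stop_invalid("`outlier_fraction` must lie in [0, 0.4]")
  if (length(total_area_range) != 2 ||
      total_area_range[1] >= total_area_range[2])
    stop_invalid("`total_area_range` must be (low, high) with low < high")
  if (zero_prob < 0 || zero_prob > 1) stop_invalid("`zero_prob` in [0, 1]")
  structure(list(
    n_colonies = as.integer(n_colonies),
    coord_coefficients = as.numeric(coord_coefficients),
    intercept = intercept, noise_sd = noise_sd,
    outlier_fraction = outlier_fraction, outlier_shift = outlier_shift,
    total_area_range = as.numeric(total_area_range),
    concentration = as.numeric(concentration),
    detection_limit_m2 = detection_limit_m2,
    zero_prob = zero_prob, seed = as.integer(seed)), class = "coda_sim_params")
}

#' Simulate a compositional regression dataset
#'
#' Draws per-colony three-part compositions from a Dirichlet, scales each by
#' a uniform total area, computes the two pivot log-ratio coordinates (pivot
#' on Live), and sets
#' `response = intercept + z %*% coord_coefficients + noise`. A seeded
#' `floor(n * outlier_fraction)` of the responses is then shifted by
#' `outlier_shift` and flagged. With `zero_prob > 0`, some colonies record
#' their smallest part as 0 (a rounded zero) while the response is still
#' generated from the true composition -- exercising the zero-replacement
#' path downstream.
#'
#' @param params a [coda_sim_params()].
#' @return A tibble with columns `colony_id`, `live_m2`, `dead_m2`,
#'   `other_m2`, `total_m2`, `detection_limit_m2`, `response`, `is_outlier`.
#'   The generating truth is attached as attributes `true_coefficients`
#'   (intercept, z1, z2) and `outlier_idx`.
#' @export
gen_coda_dataset <- function(params = coda_sim_params()) {
  stopifnot(inherits(params, "coda_sim_params"))
  p <- params
  n <- p$n_colonies
  out <- withr::with_seed(seed_stream(p$seed, 5L), {
    g <- matrix(stats::rgamma(n * 3, shape = rep(p$concentration, each = n)),
                n, 3)
    parts <- g / rowSums(g)
    totals <- runif(n, p$total_area_range[1], p$total_area_range[2])
    areas <- parts * totals
    z <- as.matrix(pivot_coordinates(parts, pivot = 1))
    resp <- p$intercept + drop(z %*% p$coord_coefficients) +
      rnorm(n, sd = p$noise_sd)
    n_out <- floor(n * p$outlier_fraction + 1e-9)
    idx <- if (n_out > 0) sort(sample.int(n, n_out)) else integer(0)
    resp[idx] <- resp[idx] + p$outlier_shift
    rec <- areas
    if (p$zero_prob > 0) {
      floor_it <- runif(n) < p$zero_prob
      jmin <- max.col(-rec, ties.method = "first")
      rec[cbind(which(floor_it), jmin[floor_it])] <- 0
    }
    list(rec = rec, totals = totals, resp = resp, idx = idx)
  })
  res <- tibble::tibble(
    colony_id = sprintf("colony_%02d", seq_len(n)),
    live_m2 = out$rec[, 1], dead_m2 = out$rec[, 2], other_m2 = out$rec[, 3],
    total_m2 = out$totals,
    detection_limit_m2 = p$detection_limit_m2,
    response = out$resp,
    is_outlier = seq_len(n) %in% out$idx
  )
  attr(res, "true_coefficients") <-
    c(intercept = p$intercept, z1 = p$coord_coefficients[1],
      z2 = p$coord_coefficients[2])
  attr(res, "outlier_idx") <- out$idx
  res
}

#' Simulate a multi-colony study
#'
#' Generates `n_colonies` colonies whose live fraction sweeps
#' `live_range` while Dead stays rougher than Live (the generator default).
#' The Other fraction is drawn per colony from `other_range`, so the two
#' log-ratio coordinates of the composition vary independently rather than
#' collinearly -- the compositional spread real surveys show (Other cover
#' spanning nearly zero to dominant). Each colony gets an irregular survey
#' footprint built as a connected union of `factor` x `factor` cell blocks
#' (block counts sampled in `footprint_blocks`), so planform areas span
#' roughly 1.2-2.5 m^2 at the default geometry -- the survey-extent range the
#' generator emulates. Footprints are block-aligned so the edge trim of
#' [colony_metrics()] leaves them unchanged.
#'
#' @param n_colonies number of colonies.
#' @param seed study seed; per-colony seeds are derived from it.
#' @param live_range swept range of the Live fraction (of the coral part).
#' @param other_range per-colony Other fraction is uniform over this range.
#' @param grid_cells grid side in cells (default 160 = 5 blocks of 32).
#' @param factor footprint block edge in cells (the coarsest aggregation
#'   factor of the metric pipeline).
#' @param footprint_blocks integer range of blocks per footprint.
#' @param ... further arguments passed to [colony_params()].
#' @return A list of colonies, each a list with `dem`, `mask`, `colony_id`,
#'   `params`.
#' @export
gen_study <- function(n_colonies = 10, seed = 1, live_range = c(0.05, 0.9),
                      other_range = c(0.05, 0.35), grid_cells = 160, factor = 32,
                      footprint_blocks = c(12, 24), ...) {
  if (!is_count(n_colonies) || n_colonies < 2)
    stop_invalid("`n_colonies` must be an integer >= 2")
  live <- seq(live_range[1], live_range[2], length.out = n_colonies)
  nb <- grid_cells %/% factor
  draws <- withr::with_seed(seed_stream(seed, 7L), {
    list(blocks = lapply(seq_len(n_colonies), function(i)
           grow_block_footprint(nb, sample(footprint_blocks[1]:footprint_blocks[2], 1))),
         other = runif(n_colonies, other_range[1], other_range[2]))
  })
  blocks <- draws$blocks
  lapply(seq_len(n_colonies), function(i) {
    lf <- live[i] * (1 - draws$other[i])
    df <- (1 - live[i]) * (1 - draws$other[i])
    p <- colony_params(live_fraction = lf, dead_fraction = df,
                       grid_cells = grid_cells,
                       seed = seed_stream(seed, 100L + i), ...)
    fp <- blocks[[i]][rep(seq_len(nb), each = factor),
                      rep(seq_len(nb), each = factor)]
    fp <- rbind(fp, matrix(FALSE, grid_cells - nrow(fp), ncol(fp)))
    fp <- cbind(fp, matrix(FALSE, grid_cells, grid_cells - ncol(fp)))
    col <- gen_colony(p, footprint = fp)
    col$colony_id <- sprintf("sim_%02d", i)
    col
  })
}

# connected block footprint grown by seeded random adjacency
grow_block_footprint <- function(nb, k) {
  k <- min(k, nb * nb)
  fp <- matrix(FALSE, nb, nb)
  start <- c(ceiling(nb / 2), ceiling(nb / 2))
  fp[start[1], start[2]] <- TRUE
  while (sum(fp) < k) {
    cur <- which(fp, arr.ind = TRUE)
    cand <- unique(rbind(cur + rep(c(1, 0), each = nrow(cur)),
                         cur + rep(c(-1, 0), each = nrow(cur)),
                         cur + rep(c(0, 1), each = nrow(cur)),
                         cur + rep(c(0, -1), each = nrow(cur))))
    cand <- cand[cand[, 1] >= 1 & cand[, 1] <= nb &
                 cand[, 2] >= 1 & cand[, 2] <= nb, , drop = FALSE]
    cand <- cand[!fp[cand], , drop = FALSE]
    pick <- cand[sample.int(nrow(cand), 1), ]
    fp[pick[1], pick[2]] <- TRUE
  }
  fp
}
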