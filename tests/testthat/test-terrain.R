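test_that("planform and geodesic areas hit their analytic anchors", {
  flat <- elev_raster(matrix(2, 100, 100), 0.01)
  expect_equal(planform_area(flat), 1.0)
  expect_equal(geodesic_area(flat), 1.0, tolerance = 1e-12)

  half <- matrix(2, 100, 100); half[sample(1e4, 50)] <- NA
  expect_equal(planform_area(elev_raster(half, 0.01)), 0.995)

  p60 <- make_plane(100, 0.01, gx = tan(60 * pi / 180))
  expect_equal(geodesic_area(p60), 2.0, tolerance = 1e-9)
  expect_gte(geodesic_area(p60), planform_area(p60))
})

test_that("rugosity is 1 for flat, sec(theta) for planes, and >= 1 always", {
  expect_equal(surface_rugosity(elev_raster(matrix(-3, 64, 64), 0.01)), 1.0)
  expect_equal(surface_rugosity(make_plane(64, 0.01, gx = 1)), sqrt(2),
               tolerance = 1e-9)
  for (s in 1:5) {
    r <- gen_fbm_dem(0.5, 64, 0.01, 0.02, seed = s)
    expect_gte(surface_rugosity(r), 1)
  }
})

test_that("geodesic area agrees with an 8-triangle Jenness-style oracle within 2%", {
  r <- gen_fbm_dem(0.5, 64, 0.01, 0.05, seed = 12)
  rug_pkg <- surface_rugosity(r)
  rug_oracle <- oracle_jenness_rugosity(r$values, 0.01)
  expect_lt(abs(rug_pkg - rug_oracle) / rug_oracle, 0.02)
})

test_that("surface-area curve matches manual per-factor computation bit-for-bit", {
  r <- gen_fbm_dem(0.5, 256, 0.01, 0.05, seed = 4)
  trimmed <- aggregate_clip(r, 32)
  cv <- surface_area_curve(trimmed)
  manual <- sapply(c(1, 2, 4, 8, 16, 32), function(f)
    geodesic_area(resample_to_grid(aggregate_clip(trimmed, f), f * 0.01)))
  expect_identical(cv$area_m2, manual)
})

test_that("log-log fit recovers an injected power law exactly", {
  res <- 0.01 * c(1, 2, 4, 8, 16, 32)
  cv <- sa_curve(res, 3.7 * res^(-0.4))
  expect_equal(attr(cv, "log_slope"), -0.4, tolerance = 1e-12)
  expect_equal(attr(cv, "r_squared"), 1, tolerance = 1e-12)
  expect_equal(fractal_dimension(cv)$d, 2.4, tolerance = 1e-12)

  cv3 <- sa_curve(res, 2 * res^(-1))
  expect_equal(fractal_dimension(cv3)$d, 3, tolerance = 1e-12)

  flat <- suppressWarnings(sa_curve(res, rep(5, 6)))
  ff <- fractal_dimension(flat)
  expect_identical(ff$d, 2)
  expect_true(ff$is_fractal)

  expect_reef_error(sa_curve(res, c(-1, 1, 1, 1, 1, 1)), "invalid_argument")
  expect_reef_error(sa_curve(res[1:2], c(1, 1)), "invalid_argument")
})

test_that("fBm surfaces show fractality over the step ladder", {
  r <- gen_fbm_dem(0.5, 512, 0.01, 2, seed = 1)
  cv <- surface_area_curve(aggregate_clip(r, 32))
  expect_gte(attr(cv, "r_squared"), 0.98)
})

test_that("the curve precondition names an offending factor", {
  r <- elev_raster(matrix(0, 64, 64), 0.01)
  expect_error(surface_area_curve(r), "32", class = "reefmorph_invalid_argument")
})

test_that("slope is exact on planes and matches the brute-force oracle", {
  p45 <- make_plane(32, 0.01, gx = 1)
  sl <- slope_cells(p45)
  expect_equal(sl[2:31, 2:31], matrix(45, 30, 30))
  expect_true(all(is.na(sl[1, ])) && all(is.na(sl[, 1])))

  expect_equal(slope_cells(elev_raster(matrix(1, 16, 16), 0.01))[5, 5], 0)

  r <- gen_fbm_dem(0.5, 64, 0.01, 0.05, seed = 8)
  orc <- oracle_slope_curv(r$values, 0.01)
  expect_equal(slope_cells(r), orc$slope, tolerance = 1e-9)
})

test_that("curvatures match the oracle cell-for-cell and vanish on planes", {
  r <- gen_fbm_dem(0.5, 64, 0.01, 0.05, seed = 8)
  orc <- oracle_slope_curv(r$values, 0.01)
  expect_equal(curvature_cells(r, "planform"), orc$plan, tolerance = 1e-9)
  expect_equal(curvature_cells(r, "profile"), orc$prof, tolerance = 1e-9)

  pl <- make_plane(16, 0.01, gx = 0.7, gy = -0.3)
  expect_lt(max(abs(curvature_cells(pl, "profile")), na.rm = TRUE), 1e-7)
  expect_lt(max(abs(curvature_cells(pl, "planform")), na.rm = TRUE), 1e-7)
  # flat: gradient vanishes, curvature 0 by convention
  expect_equal(curvature_cells(elev_raster(matrix(5, 8, 8), 0.01), "profile")[4, 4], 0)
})

test_that("profile curvature on z = x^2 matches the closed-form window expression", {
  cs <- 0.1
  n <- 16
  xs <- (seq_len(n) - 0.5) * cs
  r <- elev_raster(outer(rep(1, n), xs, function(y, x) x^2), cs)
  prof <- curvature_cells(r, "profile")
  for (j in c(3, 8, 12)) {
    x0 <- xs[j]
    dd <- ((  (x0 - cs)^2 + (x0 + cs)^2) / 2 - x0^2) / cs^2  # = 1
    g  <- ((x0 + cs)^2 - (x0 - cs)^2) / (2 * cs)             # = 2 x0
    expected <- -2 * dd * g^2 / g^2 * 100
    expect_equal(prof[5, j], expected, tolerance = 1e-9)
  }
})

test_that("planform curvature changes sign between convex and concave relief", {
  cs <- 0.1; n <- 33
  xs <- (seq_len(n) - (n + 1) / 2) * cs
  # alternating ridges and hollows: contours bend the opposite way around
  # crests (divergent, positive) and around basins (convergent, negative)
  z <- outer(xs, xs, function(y, x) 0.5 * sin(2 * pi * x / 1.6) *
                                    sin(2 * pi * y / 1.6))
  pc <- curvature_cells(elev_raster(z, cs), "planform")
  expect_gt(max(pc, na.rm = TRUE), 1)
  expect_lt(min(pc, na.rm = TRUE), -1)
})

test_that("evans curvature method is available and exact on planes", {
  pl <- make_plane(16, 0.01, gx = 0.5)
  expect_equal(slope_cells(pl, method = "evans")[8, 8], atan(0.5) * 180 / pi)
  expect_lt(max(abs(curvature_cells(pl, "profile", method = "evans")),
                na.rm = TRUE), 1e-7)
})

test_that("cell summaries follow the linear-interpolation quartile convention", {
  s <- summarize_cells(matrix(1:100, 10, 10))
  expect_equal(s$median, 50.5)
  expect_equal(s$q1, 25.75)
  expect_equal(s$q3, 75.25)
  expect_equal(s$iqr, 49.5)

  s1 <- summarize_cells(7)
  expect_true(all(unlist(s1[c("mean", "median", "min", "max", "q1", "q3")]) == 7))
  expect_equal(s1$iqr, 0)

  set.seed(3)
  v <- runif(257)
  s2 <- summarize_cells(v)
  sv <- sort(v)
  expect_identical(s2$min, sv[1])
  expect_identical(s2$max, sv[257])
  expect_identical(s2$median, sv[129])
  expect_equal(unname(unlist(s2[c("q1", "median", "q3")])),
               unname(quantile(v, c(.25, .5, .75))), tolerance = 1e-12)
  expect_reef_error(summarize_cells(rep(NA_real_, 5)), "empty_input")
})

test_that("a flat colony produces the all-trivial metric row", {
  cfg <- study_config(factors = c(1, 2, 4, 8))
  m <- colony_metrics(elev_raster(matrix(1, 128, 128), 0.01), config = cfg)
  expect_equal(m$surface_rugosity, 1)
  expect_equal(m$fractal_d, 2)
  expect_equal(m$slope_mean, 0)
  expect_equal(m$slope_iqr, 0)
  expect_equal(m$plan_curv_iqr, 0)
  expect_equal(m$prof_curv_iqr, 0)
  expect_equal(m$planform_area_m2, m$geodesic_area_m2, tolerance = 1e-12)
})

test_that("metrics are invariant to constant offsets and 180-degree rotation", {
  r <- gen_fbm_dem(0.6, 128, 0.01, 0.05, seed = 5)
  cfg <- study_config(factors = c(1, 2, 4, 8))
  m1 <- colony_metrics(r, config = cfg)
  shifted <- elev_raster(r$values + 11.7, 0.01)
  m2 <- colony_metrics(shifted, config = cfg)
  expect_equal(m2$fractal_d, m1$fractal_d, tolerance = 1e-9)
  expect_equal(m2$surface_rugosity, m1$surface_rugosity, tolerance = 1e-9)
  expect_equal(m2$slope_iqr, m1$slope_iqr, tolerance = 1e-9)
  rot <- elev_raster(r$values[128:1, 128:1], 0.01)
  m3 <- colony_metrics(rot, config = cfg)
  expect_equal(m3$fractal_d, m1$fractal_d, tolerance = 1e-9)
  expect_equal(m3$surface_rugosity, m1$surface_rugosity, tolerance = 1e-9)
  expect_equal(m3$slope_median, m1$slope_median, tolerance = 1e-9)
  expect_equal(m3$prof_curv_iqr, m1$prof_curv_iqr, tolerance = 1e-9)
})

test_that("Dead-restricted D exceeds Live-restricted D across seeds", {
  cfg <- study_config()
  wins <- sapply(1:5, function(s) {
    col <- gen_colony(colony_params(live_fraction = 0.45, dead_fraction = 0.45,
                                    seed = s))
    dl <- suppressWarnings(
      colony_metrics(col$dem, col$mask, "Live", cfg))$fractal_d
    dd <- suppressWarnings(
      colony_metrics(col$dem, col$mask, "Dead", cfg))$fractal_d
    dd > dl
  })
  expect_gte(mean(wins), 0.8)
})

test_that("a category too small to triangulate reports missing surface metrics", {
  z <- gen_fbm_dem(0.5, 64, 0.01, 0.05, seed = 1)
  lab <- matrix(2L, 64, 64)
  lab[1, 1] <- 1L # a single Live cell: no complete 2x2 block
  m <- benthic_mask(lab, 0.01)
  cfg <- study_config(factors = c(1, 2, 4))
  expect_warning(out <- colony_metrics(z, m, "Live", cfg), "smaller|metrics")
  expect_true(is.na(out$surface_rugosity))
  expect_true(is.na(out$fractal_d))
})
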