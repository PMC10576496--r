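test_that("DEM ASCII grids round-trip, with no-data preserved", {
  set.seed(42)
  z <- matrix(rnorm(64 * 64, sd = 0.05), 64, 64)
  z[5, 7] <- NA
  r <- elev_raster(z, cell_size = 0.01, origin = c(3.5, -2.25))
  path <- withr::local_tempfile(fileext = ".asc")
  write_dem(r, path)
  r2 <- read_dem(path)
  expect_equal(r2$values, r$values, tolerance = 1e-9)
  expect_identical(is.na(r2$values), is.na(r$values))
  expect_equal(r2$cell_size, r$cell_size)
  expect_equal(r2$origin, r$origin)
})

test_that("NODATA sentinel cells are excluded from metrics", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 4", "nrows 4", "xllcorner 0", "yllcorner 0",
               "cellsize 0.01", "NODATA_value -9999",
               "1 1 1 1", "1 -9999 1 1", "1 1 1 1", "1 1 1 1"), path)
  r <- read_dem(path)
  expect_equal(sum(is.na(r$values)), 1L)
  expect_equal(planform_area(r), 15 * 1e-4)
})

test_that("unsupported and malformed raster files are rejected", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 4", "nrows 4", "xllcorner 0", "yllcorner 0",
               "dx 0.01", "dy 0.02", "NODATA_value -9999",
               paste(rep("0", 16), collapse = " ")), path)
  expect_reef_error(read_dem(path), "unsupported_format")
  expect_reef_error(read_dem(withr::local_tempfile(fileext = ".xyz")),
                    "not_found")
  xyz <- withr::local_tempfile(fileext = ".xyz")
  writeLines("0 0 0", xyz)
  expect_reef_error(read_dem(xyz), "unsupported_format")
  r <- elev_raster(matrix(0, 4, 4), 0.01)
  expect_reef_error(write_dem(r, withr::local_tempfile(fileext = ".xyz")),
                    "unsupported_format")
  short <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 4", "nrows 4", "cellsize 0.01", "1 2 3"), short)
  expect_reef_error(read_dem(short), "malformed_input")
})

test_that("masks round-trip through ASCII grids with code 0 as no-data", {
  lab <- matrix(sample(c(1:3, NA), 64, replace = TRUE), 8, 8)
  m <- benthic_mask(lab, cell_size = 0.01)
  path <- withr::local_tempfile(fileext = ".asc")
  write_mask(m, path)
  m2 <- read_mask(path)
  expect_identical(m2$labels, m$labels)
})

test_that("block-mean resampling does exact arithmetic and NA propagation", {
  r <- elev_raster(matrix(1:16, 4, 4, byrow = TRUE), cell_size = 1)
  out <- resample_to_grid(r, 2)
  expect_equal(out$values, matrix(c(3.5, 11.5, 5.5, 13.5), 2, 2))
  expect_equal(out$cell_size, 2)

  rc <- elev_raster(matrix(7, 8, 8), 0.01)
  expect_true(all(resample_to_grid(rc, 0.04)$values == 7))

  z <- matrix(1, 4, 4); z[1, 1] <- NA
  rna <- resample_to_grid(elev_raster(z, 1), 2)
  expect_true(is.na(rna$values[1, 1]))
  expect_equal(rna$values[2, 2], 1)

  expect_reef_error(resample_to_grid(elev_raster(matrix(0, 4, 4), 1), 1.5),
                    "invalid_argument")
})

test_that("resampling preserves the spatial mean of fully valid rasters", {
  set.seed(7)
  z <- matrix(rnorm(64 * 64), 64, 64)
  r <- elev_raster(z, 0.01)
  for (f in c(2, 4, 8))
    expect_equal(mean(resample_to_grid(r, f * 0.01)$values), mean(z))
})

test_that("aggregate_clip nulls exactly the blocks touching no-data", {
  z <- matrix(1, 10, 10)
  z[1, 1] <- NA # 1-cell notch in the NW corner
  r <- aggregate_clip(elev_raster(z, 0.01), 2)
  expect_true(all(is.na(r$values[1:2, 1:2])))
  expect_equal(sum(!is.na(r$values)), 96)
  expect_equal(r$values[3:10, ], matrix(1, 8, 10))
})

test_that("aggregate_clip is idempotent, monotone in factor, and never adds cells", {
  set.seed(11)
  z <- matrix(rnorm(64 * 64), 64, 64)
  z[sample(64 * 64, 100)] <- NA
  r <- elev_raster(z, 0.01)
  prev <- sum(!is.na(z))
  for (f in c(1, 2, 4, 8, 16, 32)) {
    cl <- aggregate_clip(r, f)
    nv <- sum(!is.na(cl$values))
    expect_lte(nv, prev)
    prev <- nv
    again <- aggregate_clip(cl, f)
    expect_identical(again$values, cl$values)
  }
  full <- elev_raster(matrix(1, 64, 64), 0.01)
  expect_identical(aggregate_clip(full, 8)$values, full$values)
  expect_identical(aggregate_clip(r, 1)$values, r$values)
  expect_reef_error(aggregate_clip(r, 100), "invalid_argument")
})

test_that("composition areas count cells, close exactly, and keep zeros", {
  lab <- matrix(NA_integer_, 10, 10)
  lab[1:4, 1:10] <- 1L  # 40 Live
  lab[5:8, 1:10] <- 2L  # 40 Dead
  lab[9:10, 1:10] <- 3L # 20 Other
  m <- benthic_mask(lab, cell_size = 0.01)
  rec <- quantify_areas(m, "c1", detection_limit_area = 3.6e-7)
  expect_equal(rec$live_m2, 0.004)
  expect_equal(rec$dead_m2, 0.004)
  expect_equal(rec$other_m2, 0.002)
  expect_equal(rec$total_m2, rec$live_m2 + rec$dead_m2 + rec$other_m2)

  lab[lab == 3L] <- 2L # no Other cells -> rounded zero
  rec0 <- quantify_areas(benthic_mask(lab, 0.01), "c2", 3.6e-7)
  expect_identical(rec0$other_m2, 0)
  expect_equal(rec0$dead_m2, rec0$total_m2 - rec0$live_m2)

  lab[] <- 2L # whole colony dead
  recd <- quantify_areas(benthic_mask(lab, 0.01), "c3", 3.6e-7)
  expect_equal(recd$dead_m2, recd$total_m2)

  expect_reef_error(
    quantify_areas(benthic_mask(matrix(NA_integer_, 8, 8), 0.01)),
    "empty_input")
})

test_that("GeoJSON polygons rasterize by cell-centre membership with first-listed precedence", {
  template <- elev_raster(matrix(0, 10, 10), cell_size = 0.1)
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(category = "Live"),
         geometry = list(type = "Polygon",
                         coordinates = list(list(list(0, 0), list(0.6, 0),
                                                 list(0.6, 1), list(0, 1),
                                                 list(0, 0))))),
    list(type = "Feature", properties = list(category = "Dead"),
         geometry = list(type = "Polygon",
                         coordinates = list(list(list(0.4, 0), list(1, 0),
                                                 list(1, 1), list(0.4, 1),
                                                 list(0.4, 0)))))
  ))
  path <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE)
  m <- mask_from_geojson(path, template)
  # columns 1-6 have centres x < 0.6 -> Live wins (listed first) on overlap
  expect_true(all(m$labels[, 1:6] == 1L))
  expect_true(all(m$labels[, 7:10] == 2L))
})
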