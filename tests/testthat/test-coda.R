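make_records <- function(parts, dl = 3.6e-7) {
  tibble::tibble(colony_id = sprintf("c%02d", seq_len(nrow(parts))),
                 live_m2 = parts[, 1], dead_m2 = parts[, 2],
                 other_m2 = parts[, 3],
                 detection_limit_m2 = dl)
}

test_that("rounded zeros are replaced by alpha x detection limit; others untouched", {
  rec <- make_records(rbind(c(0.5, 0.7, 0)), dl = 3.6e-7)
  out <- replace_rounded_zeros(rec, alpha = 0.05)
  expect_equal(out$other_m2, 1.8e-8)
  expect_identical(out$live_m2, 0.5)
  expect_identical(out$dead_m2, 0.7)

  clean <- make_records(rbind(c(0.4, 0.3, 0.2), c(1, 1, 1)))
  expect_identical(replace_rounded_zeros(clean), clean)

  expect_reef_error(replace_rounded_zeros(make_records(rbind(c(-1, 1, 1)))),
                    "invalid_argument")
})

test_that("closed multiplicative substitution preserves record totals", {
  rec <- make_records(rbind(c(0, 0.6, 0.4)), dl = 0.2)
  out <- replace_rounded_zeros(rec, alpha = 0.05, mode = "closed_multiplicative")
  # replacement = 0.05 * 0.2 = 0.01; nonzero parts scaled by 0.99
  expect_equal(out$live_m2, 0.01)
  expect_equal(out$dead_m2, 0.594)
  expect_equal(out$other_m2, 0.396)
  expect_equal(out$live_m2 + out$dead_m2 + out$other_m2, 1.0)
  expect_true(all(as.matrix(out[c("live_m2", "dead_m2", "other_m2")]) > 0))
})

test_that("pivot coordinates hit closed forms and are scale invariant", {
  expect_equal(as.numeric(pivot_coordinates(rbind(c(1, 1, 1)))), c(0, 0))

  z <- pivot_coordinates(rbind(c(exp(1), 1, 1)), pivot = 1)
  expect_equal(z$z1, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(z$z2, 0)

  set.seed(1)
  x <- matrix(rexp(30) + 0.01, 10, 3)
  expect_equal(pivot_coordinates(x), pivot_coordinates(x * 1e3),
               tolerance = 1e-12)

  expect_reef_error(pivot_coordinates(rbind(c(0, 1, 1))), "invalid_argument")
})

test_that("LTS with h = n reproduces ordinary least squares", {
  set.seed(21)
  x <- matrix(rnorm(24), 12, 2)
  y <- 2 + x %*% c(1, -3) + rnorm(12)
  f <- lts_fit(x, y, h = 12)
  expect_equal(unname(f$coefficients), unname(coef(lm(y ~ x))),
               tolerance = 1e-10)
  expect_equal(f$objective, sum(resid(lm(y ~ x))^2), tolerance = 1e-10)
})

test_that("the fast algorithm attains the exhaustive LTS objective", {
  for (s in 1:5) {
    set.seed(s)
    n <- 12
    x <- matrix(rnorm(2 * n), n, 2)
    y <- 1 + x %*% c(2, -1) + rnorm(n, sd = 0.3)
    y[1:2] <- y[1:2] + 20
    h <- floor((n + 3 + 1) / 2)
    exact <- lts_fit(x, y, method = "exact")
    fast <- lts_fit(x, y, method = "fast", nstarts = 500, seed = s)
    oracle <- oracle_lts_objective(x, y, h)
    expect_equal(exact$objective, oracle, tolerance = 1e-8)
    expect_equal(fast$objective, oracle, tolerance = 1e-8)
  }
})

test_that("the exact objective never exceeds the MASS::lqs criterion", {
  skip_if_not_installed("MASS")
  for (s in 1:3) {
    set.seed(100 + s)
    x <- matrix(rnorm(20), 10, 2)
    y <- 1 + x %*% c(1, 1) + rnorm(10, sd = 0.2)
    y[1] <- y[1] + 30
    h <- floor((10 + 3 + 1) / 2)
    f <- lts_fit(x, y, h = h)
    lq <- MASS::lqs(x, y, method = "lts", quantile = h, nsamp = "exact")
    expect_lte(f$objective, sum(sort(resid(lq)^2)[seq_len(h)]) + 1e-8)
  }
})

test_that("LTS retains its fit under gross contamination while OLS diverges", {
  set.seed(5)
  x <- matrix(rnorm(20), 10, 2)
  beta <- c(1, 2, -1)
  y0 <- beta[1] + x %*% beta[-1] + rnorm(10, sd = 0.1)
  clean <- lts_fit(x, y0)
  err_prev <- NULL
  for (mag in c(10, 100, 1000)) {
    y <- y0; y[1] <- y[1] + mag
    f <- lts_fit(x, y)
    expect_false(1 %in% f$subset)
    expect_lt(max(abs(f$coefficients - clean$coefficients)), 3 * max(f$se))
    ols_err <- abs(coef(lm(y ~ x))[1] - beta[1])
    if (!is.null(err_prev)) expect_gt(ols_err, err_prev)
    err_prev <- ols_err
  }
})

test_that("LTS rejects impossible designs and trimming counts", {
  x <- matrix(rnorm(12), 6, 2)
  expect_reef_error(lts_fit(x, rnorm(6), h = 2), "invalid_argument")
  expect_reef_error(lts_fit(matrix(1, 8, 1), rnorm(8)), "singular_design")
  expect_reef_error(lts_fit(matrix(rnorm(4), 2, 2), rnorm(2)), "invalid_argument")
})

test_that("constant responses yield null effects with p = 1", {
  set.seed(2)
  rec <- make_records(matrix(rexp(30) + 0.1, 10, 3))
  eff <- coda_metric_regression(rec, rep(3.3, 10))
  expect_equal(eff$delta_y_per_m2, rep(0, 3))
  expect_equal(eff$p_value, rep(1, 3))
})

test_that("the three pivot rotations share fitted values and objective", {
  set.seed(8)
  parts <- matrix(rexp(36) + 0.05, 12, 3)
  rec <- make_records(parts)
  y <- 2 + 0.5 * pivot_coordinates(parts, 1)$z1 + rnorm(12, sd = 0.1)
  fits <- lapply(1:3, function(j)
    lts_fit(as.matrix(pivot_coordinates(parts, j)), y, seed = 1))
  for (j in 2:3) {
    expect_equal(fits[[j]]$fitted, fits[[1]]$fitted, tolerance = 1e-9)
    expect_equal(fits[[j]]$objective, fits[[1]]$objective, tolerance = 1e-9)
    expect_identical(fits[[j]]$subset, fits[[1]]$subset)
  }
})

test_that("coefficient bias shrinks with sample size under 10% contamination", {
  bias <- sapply(c(20, 80), function(n) {
    est <- sapply(1:20, function(s) {
      d <- gen_coda_dataset(coda_sim_params(
        n_colonies = n, coord_coefficients = c(0.5, 0), noise_sd = 0.1,
        outlier_fraction = 0.1, outlier_shift = 2, seed = 1000 * n + s))
      z <- pivot_coordinates(d, 1)
      lts_fit(as.matrix(z), d$response, seed = s, nstarts = 100)$coefficients[2]
    })
    abs(mean(est) - 0.5)
  })
  expect_lt(bias[2], bias[1] + 0.02)
  expect_lt(bias[2], 0.05)
})

test_that("tidy and glance expose the fit in broom shape", {
  set.seed(4)
  x <- matrix(rnorm(20), 10, 2)
  f <- lts_fit(x, 1 + x %*% c(1, 1) + rnorm(10, sd = 0.2))
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(td), 3)
  gl <- glance(f)
  expect_equal(gl$h, f$h)
  expect_equal(gl$objective, f$objective)
})

test_that("effects tables carry the significance marks of the results layout", {
  eff <- tibble::tibble(part = benthic_categories(),
                        coord_coef = c(-0.1, 0.2, 0.1),
                        delta_y_per_m2 = c(-0.0148, -0.0047, 0.0195),
                        sem = c(0.0056, 0.0063, 0.0096),
                        p_value = c(0.038, 0.489, 0.090))
  tab <- effects_report(list(`Fractal Dimension` = eff))
  expect_equal(tab$signif, c("*", "", "."))
  md <- effects_report(list(`Fractal Dimension` = eff), format = "markdown")
  expect_true(any(grepl("\\*", md)))
  expect_reef_error(effects_report(list()), "empty_input")
})
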