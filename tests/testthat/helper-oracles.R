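# Independent oracles, deliberately coded along different paths than the
# package internals (loops instead of shifted matrices, lm() instead of
# lm.fit, per-cell triangle fans instead of the block mesh).

# Hurst exponent from the structure function E[(z(x+h) - z(x))^2] ~ h^(2H)
oracle_variogram_hurst <- function(z, maxlag = 8) {
  g <- sapply(seq_len(maxlag), function(l) {
    dx <- z[, -(1:l), drop = FALSE] - z[, seq_len(ncol(z) - l), drop = FALSE]
    dy <- z[-(1:l), , drop = FALSE] - z[seq_len(nrow(z) - l), , drop = FALSE]
    mean(c(dx^2, dy^2))
  })
  unname(coef(lm(log(g) ~ log(seq_len(maxlag))))[2] / 2)
}

# brute-force per-cell 3x3 slope/curvature, plain loops
oracle_slope_curv <- function(z, cs) {
  nr <- nrow(z); nc <- ncol(z)
  slope <- plan <- prof <- matrix(NA_real_, nr, nc)
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    w <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (anyNA(w)) next
    gx <- (w[2, 3] - w[2, 1]) / (2 * cs)
    gy <- (w[1, 2] - w[3, 2]) / (2 * cs)
    slope[i, j] <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
    dd <- ((w[2, 1] + w[2, 3]) / 2 - w[2, 2]) / cs^2
    ee <- ((w[1, 2] + w[3, 2]) / 2 - w[2, 2]) / cs^2
    ff <- (-w[1, 1] + w[1, 3] + w[3, 1] - w[3, 3]) / (4 * cs^2)
    g2 <- gx^2 + gy^2
    if (g2 < 1e-12) {
      prof[i, j] <- 0; plan[i, j] <- 0
    } else {
      prof[i, j] <- -2 * (dd * gx^2 + ee * gy^2 + ff * gx * gy) / g2 * 100
      plan[i, j] <-  2 * (dd * gy^2 + ee * gx^2 - ff * gx * gy) / g2 * 100
    }
  }
  list(slope = slope, plan = plan, prof = prof)
}

# Jenness-style per-cell surface area: 8 triangles from the cell centre to
# midpoints toward the 8 neighbours, summed over interior cells
oracle_jenness_rugosity <- function(z, cs) {
  nr <- nrow(z); nc <- ncol(z)
  offs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1)) # N, NE, E, SE, ...
  tri_area <- function(p, q, r) {
    u <- q - p; v <- r - p
    0.5 * sqrt(sum(c(u[2] * v[3] - u[3] * v[2],
                     u[3] * v[1] - u[1] * v[3],
                     u[1] * v[2] - u[2] * v[1])^2))
  }
  total <- 0; used <- 0
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    w <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (anyNA(w)) next
    ctr <- c(0, 0, z[i, j])
    mids <- lapply(seq_len(8), function(k) {
      di <- offs[k, 1]; dj <- offs[k, 2]
      zn <- z[i + di, j + dj]
      c(dj * cs / 2, -di * cs / 2, (z[i, j] + zn) / 2)
    })
    for (k in seq_len(8)) {
      k2 <- if (k == 8) 1 else k + 1
      total <- total + tri_area(ctr, mids[[k]], mids[[k2]])
    }
    used <- used + 1
  }
  total / (used * cs^2)
}

# 4-connected component count per category code, BFS flood fill
oracle_component_count <- function(labels, code) {
  nr <- nrow(labels); nc <- ncol(labels)
  seen <- matrix(FALSE, nr, nc)
  target <- !is.na(labels) & labels == code
  comps <- 0
  for (s in which(target)) {
    if (seen[s]) next
    comps <- comps + 1
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      i <- (cur - 1) %% nr + 1; j <- (cur - 1) %/% nr + 1
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        idx <- (jj - 1) * nr + ii
        if (target[idx] && !seen[idx]) { seen[idx] <- TRUE; queue <- c(queue, idx) }
      }
    }
  }
  comps
}

# exact LTS objective by exhaustive h-subset enumeration with lm()
oracle_lts_objective <- function(x, y, h) {
  n <- length(y)
  subsets <- combn(n, h)
  best <- Inf
  for (k in seq_len(ncol(subsets))) {
    idx <- subsets[, k]
    fit <- lm(y[idx] ~ x[idx, , drop = FALSE])
    obj <- sum(resid(fit)^2)
    if (obj < best) best <- obj
  }
  best
}

# inclined plane raster: z = gx * x + gy * y (x east, y north)
make_plane <- function(n = 64, cell = 0.01, gx = 0, gy = 0, z0 = 0) {
  xs <- (seq_len(n) - 0.5) * cell
  ys <- rev(xs) # row 1 is north
  z <- z0 + outer(ys, xs, function(y, x) gx * x + gy * y)
  elev_raster(z, cell_size = cell)
}

expect_reef_error <- function(expr, class) {
  expect_error(expr, class = paste0("reefmorph_", class))
}
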