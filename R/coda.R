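#' Replace rounded zeros in composition records
#'
#' A category recorded as 0 m^2 is a rounded zero: the part may be present
#' but below the detection limit (the area of one native pixel). Before any
#' log-ratio transformation each zero part is replaced by
#' `alpha * detection_limit_m2` (default `alpha = 0.05`), the multiplicative
#' substitution rule. In the default `simple_substitution` mode nonzero
#' parts are untouched -- appropriate here because the compositions are not
#' closed (total colony areas vary freely). `closed_multiplicative` instead
#' rescales the nonzero parts by `1 - sum(replacements) / total` so each
#' record's total is preserved.
#'
#' Records without zeros are returned bit-identical.
#'
#' @param records tibble with columns `live_m2`, `dead_m2`, `other_m2`,
#'   `detection_limit_m2` (e.g. from [quantify_areas()] or
#'   [gen_coda_dataset()]).
#' @param alpha substitution fraction of the detection limit, in (0, 1).
#' @param mode `"simple_substitution"` (default) or `"closed_multiplicative"`.
#' @return `records` with all area parts strictly positive.
#' @export
replace_rounded_zeros <- function(records, alpha = 0.05,
                                  mode = c("simple_substitution",
                                           "closed_multiplicative")) {
  mode <- match.arg(mode)
  cols <- c("live_m2", "dead_m2", "other_m2")
  if (!all(c(cols, "detection_limit_m2") %in% names(records)))
    stop_invalid("records must have live_m2/dead_m2/other_m2/detection_limit_m2")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_invalid("`alpha` must lie in (0, 1)")
  parts <- as.matrix(records[cols])
  if (any(parts < 0)) stop_invalid("areas must be non-negative")
  dl <- records$detection_limit_m2
  if (any(dl <= 0)) stop_invalid("detection limits must be positive")
  zero <- parts == 0
  if (!any(zero)) return(records)
  repl <- alpha * dl                       # per-record replacement value
  replm <- matrix(repl, nrow(parts), 3)
  if (mode == "closed_multiplicative") {
    tot <- rowSums(parts)
    scale_r <- 1 - rowSums(zero) * repl / tot
    parts <- parts * scale_r
  }
  parts[zero] <- replm[zero]
  records[cols] <- as.data.frame(parts)
  records
}

#' Pivot (ilr) log-ratio coordinates of a three-part composition
#'
#' Orthonormal log-ratio coordinates in which the first coordinate isolates
#' the pivot part's relative dominance over the other two:
#' `z1 = sqrt(2/3) * ln(x_j / sqrt(x_k * x_l))` and
#' `z2 = sqrt(1/2) * ln(x_k / x_l)`, with `(k, l)` the remaining parts in
#' fixed category order. Scale-invariant: `pivot(lambda * x) = pivot(x)` for
#' any `lambda > 0`, so raw areas and closed proportions give identical
#' coordinates.
#'
#' @param x matrix, data frame or tibble of three positive parts per row
#'   (columns in Live, Dead, Other order), or a records tibble with
#'   `live_m2`/`dead_m2`/`other_m2` columns.
#' @param pivot index (1-3) or name of the pivot part.
#' @return A tibble with columns `z1`, `z2`.
#' @export
pivot_coordinates <- function(x, pivot = 1) {
  if (is.data.frame(x) && all(c("live_m2", "dead_m2", "other_m2") %in% names(x)))
    x <- x[c("live_m2", "dead_m2", "other_m2")]
  x <- as.matrix(x)
  if (ncol(x) != 3) stop_invalid("`x` must have three parts per row")
  if (is.character(pivot)) pivot <- match(pivot, benthic_categories())
  if (!pivot %in% 1:3) stop_invalid("`pivot` must identify one of the 3 parts")
  if (any(!is.finite(x)) || any(x <= 0))
    stop_invalid("all parts must be strictly positive; replace rounded zeros first")
  rest <- setdiff(1:3, pivot)          # remaining parts in fixed order
  tibble::tibble(
    z1 = sqrt(2 / 3) * log(x[, pivot] / sqrt(x[, rest[1]] * x[, rest[2]])),
    z2 = sqrt(1 / 2) * log(x[, rest[1]] / x[, rest[2]])
  )
}

#' Least trimmed squares (LTS) robust regression
#'
#' Minimizes, over coefficients `beta`, the sum of the `h` smallest squared
#' residuals -- a high-breakdown alternative to least squares. For small
#' problems (`n <= 15`) the exact solution is found by exhaustive
#' enumeration of all h-subsets (each subset's own OLS fit evaluated on that
#' subset); larger problems use the FAST-LTS concentration algorithm:
#' seeded random `p + 1`-point elemental starts, two concentration steps
#' each, and full convergence iterations from the best candidates.
#'
#' Inference comes from the reweighted step: residuals from the raw LTS fit
#' are scaled by the consistency-corrected LTS scale, observations with
#' `|r| / scale <= 2.5` get weight 1, and classical weighted-OLS standard
#' errors and t-based p-values are computed on the retained set. With
#' `h = n` the fit reduces to ordinary least squares exactly.
#'
#' @param x numeric matrix (or data frame) of predictors, without an
#'   intercept column; an intercept is always included.
#' @param y numeric response.
#' @param h trimming count, between `p + 1` and `n`; default
#'   `floor((n + p + 1) / 2)` (maximum breakdown), `p` counting the
#'   intercept.
#' @param method `"auto"` (exact for `n <= 15`, else fast), `"exact"`, or
#'   `"fast"`.
#' @param nstarts number of random elemental starts for FAST-LTS.
#' @param seed seed for the elemental starts (fast method only).
#' @return An object of class `lts_fit` with elements `coefficients`
#'   (reweighted), `raw_coefficients`, `h`, `objective` (sum of the `h`
#'   smallest squared residuals under the raw fit), `subset` (indices of the
#'   `h` retained observations), `scale`, `weights`, `se`, `p_values`,
#'   `df`, `fitted`, `residuals`, `n`, `p`. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
lts_fit <- function(x, y, h = NULL, method = c("auto", "exact", "fast"),
                    nstarts = 500, seed = 1) {
  method <- match.arg(method)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(x) != n) stop_invalid("`x` and `y` sizes differ")
  X <- cbind(`(Intercept)` = 1, x)
  p <- ncol(X)
  if (n < p + 2) stop_invalid("need n >= p + 2 observations")
  if (is.null(h)) h <- floor((n + p + 1) / 2)
  if (!is_count(h) || h < p + 1 || h > n)
    stop_invalid(sprintf("`h` must be an integer in [%d, %d]", p + 1, n))
  h <- as.integer(h)

  subset_ols <- function(idx) {
    fit <- tryCatch(stats::lm.fit(X[idx, , drop = FALSE], y[idx]),
                    error = function(e) NULL)
    if (is.null(fit) || fit$rank < p) return(NULL)
    fit$coefficients
  }
  obj_of <- function(beta) {
    r2 <- (y - drop(X %*% beta))^2
    idx <- order(r2)[seq_len(h)]
    list(obj = sum(r2[idx]), subset = sort(idx))
  }

  if (h == n) {
    beta <- subset_ols(seq_len(n))
    if (is.null(beta)) stop_singular("design matrix is rank deficient")
    best <- list(beta = beta, subset = seq_len(n),
                 obj = sum((y - drop(X %*% beta))^2))
  } else if (method == "exact" || (method == "auto" && n <= 15)) {
    subsets <- utils::combn(n, h)
    best <- NULL
    for (k in seq_len(ncol(subsets))) {
      idx <- subsets[, k]
      beta <- subset_ols(idx)
      if (is.null(beta)) next
      obj <- sum((y[idx] - drop(X[idx, , drop = FALSE] %*% beta))^2)
      if (is.null(best) || obj < best$obj)
        best <- list(beta = beta, subset = idx, obj = obj)
    }
    if (is.null(best)) stop_singular("all h-subsets are rank deficient")
    # the optimal subset is self-consistent: re-rank residuals under beta
    oo <- obj_of(best$beta)
    if (oo$obj < best$obj) best <- list(beta = best$beta, subset = oo$subset,
                                        obj = oo$obj)
  } else {
    c_step <- function(beta) {
      repeat_subset <- obj_of(beta)$subset
      nb <- subset_ols(repeat_subset)
      if (is.null(nb)) NULL else list(beta = nb, subset = repeat_subset)
    }
    cands <- withr::with_seed(seed, {
      out <- vector("list", nstarts)
      for (s in seq_len(nstarts)) {
        beta <- NULL
        for (try in 1:20) {
          el <- sample.int(n, min(p + 1, n))
          beta <- subset_ols(el)
          if (!is.null(beta)) break
        }
        if (is.null(beta)) next
        for (cs in 1:2) {                 # two concentration steps per start
          st <- c_step(beta)
          if (is.null(st)) break
          beta <- st$beta
        }
        if (!is.null(beta)) out[[s]] <- list(beta = beta, obj = obj_of(beta)$obj)
      }
      out
    })
    cands <- Filter(Negate(is.null), cands)
    if (length(cands) == 0) stop_singular("no non-singular elemental start found")
    ord <- order(vapply(cands, `[[`, 0, "obj"))
    best <- NULL
    for (k in head(ord, 10)) {            # refine the 10 best to convergence
      beta <- cands[[k]]$beta
      prev <- NULL
      for (iter in 1:100) {
        st <- c_step(beta)
        if (is.null(st)) break
        beta <- st$beta
        if (!is.null(prev) && identical(prev, st$subset)) break
        prev <- st$subset
      }
      oo <- obj_of(beta)
      if (is.null(best) || oo$obj < best$obj)
        best <- list(beta = beta, subset = oo$subset, obj = oo$obj)
    }
  }

  raw_beta <- best$beta
  r_raw <- y - drop(X %*% raw_beta)
  a <- h / n
  consistency <- if (h == n) 1 else {
    q <- qnorm((1 + a) / 2)
    sqrt(1 - 2 * q * dnorm(q) / a)                # trimmed-normal variance
  }
  scale_raw <- sqrt(best$obj / h) / consistency
  w <- if (scale_raw > 0) as.numeric(abs(r_raw) / scale_raw <= 2.5)
       else as.numeric(abs(r_raw) <= 1e-12)
  if (sum(w) < p) w <- as.numeric(seq_len(n) %in% best$subset)
  wfit <- stats::lm.wfit(X, y, w)
  beta <- wfit$coefficients
  r <- y - drop(X %*% beta)
  sw <- sum(w)
  df <- sw - p
  if (df > 0) {
    sigma2 <- sum(w * r^2) / df
    XtX <- crossprod(X * sqrt(w))
    covb <- tryCatch(sigma2 * solve(XtX), error = function(e) NULL)
    se <- if (is.null(covb)) rep(NA_real_, p) else sqrt(diag(covb))
    tval <- beta / se
    pv <- 2 * pt(-abs(tval), df)
  } else {
    se <- rep(NA_real_, p); pv <- rep(NA_real_, p)
  }
  structure(list(
    coefficients = beta, raw_coefficients = raw_beta, h = h,
    objective = best$obj, subset = best$subset, scale = scale_raw,
    weights = w, se = stats::setNames(se, names(beta)),
    p_values = stats::setNames(pv, names(beta)), df = df,
    fitted = drop(X %*% beta), residuals = r, n = n, p = p,
    method = method), class = "lts_fit")
}

#' @export
print.lts_fit <- function(x, ...) {
  cat(sprintf("<lts_fit> n = %d, h = %d, objective = %.6g, scale = %.4g\n",
              x$n, x$h, x$objective, x$scale))
  print(tidy.lts_fit(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname lts_fit
#' @param x an `lts_fit`.
#' @param ... unused.
#' @method tidy lts_fit
#' @export
tidy.lts_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(x$se),
                 statistic = unname(x$coefficients / x$se),
                 p.value = unname(x$p_values))
}

#' @rdname lts_fit
#' @method glance lts_fit
#' @export
glance.lts_fit <- function(x, ...) {
  tibble::tibble(n = x$n, h = x$h, objective = x$objective, scale = x$scale,
                 n.weighted = sum(x$weights), df.residual = x$df)
}

#' Robust compositional regression of a structural metric
#'
#' Regresses a per-colony structural metric on benthic composition: for each
#' part `j` (Live, Dead, Other), the three-part composition is expressed in
#' pivot coordinates with `j` as pivot, the metric is fit on
#' `(1, z1, z2)` by least trimmed squares, and the `z1` coefficient -- the
#' effect of part `j`'s relative dominance -- is reported with its standard
#' error and p-value. The three pivot fits are rotations of one coordinate
#' system, so their fitted values, residuals and LTS objective coincide
#' (asserted; the same elemental-start seed guarantees it for the fast
#' method too).
#'
#' `delta_y_per_m2` converts the coordinate effect to the practical scale: a
#' finite-difference prediction
#' `yhat(xbar + 1 m^2 * e_j) - yhat(xbar)` at the part-wise mean composition
#' `xbar`, i.e. the predicted change in the metric when one square metre of
#' category `j` is added and the other areas are held fixed. The raw
#' coordinate coefficient is always reported alongside.
#'
#' @param records zero-replaced composition records (all parts positive).
#' @param y numeric metric values, one per record.
#' @param h,nstarts,seed passed to [lts_fit()].
#' @return A tibble of class `reef_effects`: one row per part with
#'   `part`, `coord_coef`, `delta_y_per_m2`, `sem`, `p_value`.
#' @export
coda_metric_regression <- function(records, y, h = NULL, nstarts = 500,
                                   seed = 1) {
  cols <- c("live_m2", "dead_m2", "other_m2")
  if (!all(cols %in% names(records)))
    stop_invalid("records must have live_m2/dead_m2/other_m2 columns")
  parts <- as.matrix(records[cols])
  n <- nrow(parts)
  y <- as.numeric(y)
  if (length(y) != n) stop_invalid("`y` must have one value per record")
  if (n < 6) stop_invalid("need at least 6 colonies for the regression stage")
  out <- tibble::tibble(part = benthic_categories(),
                        coord_coef = NA_real_, delta_y_per_m2 = NA_real_,
                        sem = NA_real_, p_value = NA_real_)
  if (var(y) == 0) {                      # constant response: null effects
    out$coord_coef <- 0; out$delta_y_per_m2 <- 0; out$p_value <- 1
    class(out) <- c("reef_effects", class(out))
    return(out)
  }
  xbar <- colMeans(parts)
  fits <- vector("list", 3)
  for (j in 1:3) {
    z <- as.matrix(pivot_coordinates(parts, pivot = j))
    fits[[j]] <- lts_fit(z, y, h = h, method = "auto", nstarts = nstarts,
                         seed = seed)
    z0 <- as.matrix(pivot_coordinates(rbind(xbar), pivot = j))
    z1p <- as.matrix(pivot_coordinates(rbind(xbar + (1:3 == j)), pivot = j))
    out$coord_coef[j] <- unname(fits[[j]]$coefficients[2])
    out$delta_y_per_m2[j] <-
      drop((z1p - z0) %*% fits[[j]]$coefficients[2:3])
    out$sem[j] <- unname(fits[[j]]$se[2])
    out$p_value[j] <- unname(fits[[j]]$p_values[2])
  }
  # pivot rotations share fitted values and objective
  for (j in 2:3) {
    if (max(abs(fits[[j]]$fitted - fits[[1]]$fitted)) > 1e-6)
      warn("pivot rotations disagree; the LTS search may not have converged")
  }
  attr(out, "fits") <- fits
  attr(out, "n") <- n
  class(out) <- c("reef_effects", class(out))
  out
}

#' Format per-metric component effect tables
#'
#' Stacks one effect table per structural metric into the standard results
#' layout: one block per metric, one row per benthic part, with the
#' predicted change per added m^2, its SEM, the p-value, and significance
#' marks `*` (p < 0.05) and `.` (p < 0.10).
#'
#' @param tables named list of `reef_effects` tibbles (names are metric
#'   labels), or a single `reef_effects`.
#' @param path optional CSV output path.
#' @param format `"tibble"` (default) or `"markdown"` (returns a character
#'   vector of table lines).
#' @return The combined table (invisibly when written to `path`).
#' @export
effects_report <- function(tables, path = NULL,
                           format = c("tibble", "markdown")) {
  format <- match.arg(format)
  if (inherits(tables, "reef_effects")) tables <- list(metric = tables)
  if (length(tables) == 0) stop_empty("no effect tables supplied")
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop_invalid("`tables` must be a named list of effect tables")
  tab <- dplyr::bind_rows(lapply(names(tables), function(nm) {
    t <- tables[[nm]]
    if (!all(c("part", "delta_y_per_m2", "sem", "p_value") %in% names(t)))
      stop_invalid("each table needs part/delta_y_per_m2/sem/p_value")
    dplyr::mutate(tibble::as_tibble(t), metric = nm, .before = 1)
  }))
  tab$signif <- dplyr::case_when(
    is.na(tab$p_value) ~ "",
    tab$p_value < 0.05 ~ "*",
    tab$p_value < 0.10 ~ ".",
    TRUE ~ ""
  )
  tab <- tab[c("metric", "part", "delta_y_per_m2", "sem", "p_value", "signif")]
  if (!is.null(path)) {
    readr::write_csv(tab, path)
    return(invisible(tab))
  }
  if (format == "markdown") {
    lines <- c("| Metric | Benthos | dy/m2 | SEM | p |  |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %s | %.4g | %.4g | %.4g | %s |",
                       tab$metric, tab$part, tab$delta_y_per_m2, tab$sem,
                       tab$p_value, tab$signif))
    return(lines)
  }
  tab
}
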