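#' Study configuration
#'
#' Houses every tunable setting of the analysis pipeline with the standard
#' defaults: metrics on a 1 cm working grid, surface-area steps at working
#' cell sizes of 1-32 cm (aggregation factors 1, 2, 4, 8, 16, 32), a 0.98
#' linearity threshold for the fractality check, Zevenbergen-Thorne
#' slope/curvature, zero replacement at `alpha = 0.05` of the detection
#' limit, and maximum-breakdown LTS trimming.
#'
#' @param working_cell_size working grid cell size in metres.
#' @param factors aggregation factors of the surface-area ladder.
#' @param linearity_threshold minimum log-log R^2 for `is_fractal`.
#' @param curvature_method `"zevenbergen_thorne"` or `"evans"`.
#' @param zero_alpha rounded-zero substitution fraction.
#' @param zero_mode `"simple_substitution"` or `"closed_multiplicative"`.
#' @param trim_h LTS trimming count `h`, or `NULL` for the
#'   maximum-breakdown default.
#' @param seed seed for the stochastic parts of the LTS search.
#' @param output_dir optional directory for pipeline outputs.
#' @return A list of class `study_config`.
#' @export
study_config <- function(working_cell_size = 0.01,
                         factors = c(1, 2, 4, 8, 16, 32),
                         linearity_threshold = 0.98,
                         curvature_method = c("zevenbergen_thorne", "evans"),
                         zero_alpha = 0.05,
                         zero_mode = "simple_substitution",
                         trim_h = NULL, seed = 1, output_dir = NULL) {
  curvature_method <- match.arg(curvature_method)
  if (working_cell_size <= 0) stop_invalid("`working_cell_size` must be positive")
  if (length(factors) < 3 || any(!vapply(factors, is_count, TRUE)))
    stop_invalid("`factors` must be >= 3 positive integers")
  structure(list(
    working_cell_size = working_cell_size,
    factors = as.integer(sort(factors)),
    linearity_threshold = linearity_threshold,
    curvature_method = curvature_method,
    zero_alpha = zero_alpha, zero_mode = zero_mode,
    trim_h = trim_h, seed = as.integer(seed),
    output_dir = output_dir), class = "study_config")
}

#' Read and write a study configuration as YAML
#'
#' The file representation round-trips losslessly through
#' `read_study_config(write_study_config(cfg, path))`.
#'
#' @param config a [study_config()].
#' @param path YAML file path.
#' @return `write_study_config()` returns `path`; `read_study_config()`
#'   returns a [study_config()].
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  yaml::write_yaml(unclass(config), path)
  path
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop_not_found(paste0("file not found: ", path))
  v <- yaml::read_yaml(path)
  do.call(study_config, v[!vapply(v, is.null, TRUE)])
}

#' Process one colony: metrics plus composition
#'
#' The per-colony stage of the study: read (or accept) a DEM and optional
#' mask, bring the DEM to the working grid by block-mean aggregation, run
#' the structural-metric battery (which applies the coarsest-factor edge
#' trim), and quantify benthic composition from the mask with the detection
#' limit set to one native pixel (GSD squared). Without a mask, metrics are
#' computed and the composition record is empty, with a warning.
#'
#' @param dem an [elev_raster()] or path to a DEM file.
#' @param mask a [benthic_mask()], path to a mask file (`.asc` or
#'   `.geojson`), or `NULL`.
#' @param config a [study_config()].
#' @param colony_id identifier for the colony.
#' @return A list with `metrics` (one-row tibble), `composition` (one-row
#'   tibble or `NULL`) and `provenance` (inputs, grid and configuration
#'   actually used).
#' @export
run_colony <- function(dem, mask = NULL, config = study_config(),
                       colony_id = "colony") {
  dem_path <- NULL
  if (is.character(dem)) { dem_path <- dem; dem <- read_dem(dem) }
  stopifnot(inherits(dem, "elev_raster"))
  mask_path <- NULL
  if (is.character(mask)) {
    mask_path <- mask
    mask <- if (tolower(tools::file_ext(mask)) %in% c("geojson", "json"))
      mask_from_geojson(mask, dem) else read_mask(mask)
  }
  native_gsd <- dem$gsd
  if (dem$cell_size < config$working_cell_size - 1e-12) {
    dem <- resample_to_grid(dem, config$working_cell_size)
    if (!is.null(mask)) mask <- resample_mask_majority(mask, config$working_cell_size)
  }
  if (!is.null(mask)) check_aligned(dem, mask)
  metrics <- colony_metrics(dem, mask = mask, config = config,
                            colony_id = colony_id)
  composition <- NULL
  if (is.null(mask)) {
    warn(sprintf("colony %s: no mask supplied; composition not quantified",
                 colony_id))
  } else {
    composition <- quantify_areas(mask, colony_id,
                                  detection_limit_area = native_gsd^2)
    composition$gsd_m <- native_gsd
  }
  provenance <- list(
    colony_id = colony_id, dem_path = dem_path, mask_path = mask_path,
    dem_md5 = if (!is.null(dem_path)) unname(tools::md5sum(dem_path)) else NA,
    grid = dim(dem$values), cell_size = dem$cell_size, native_gsd = native_gsd,
    config = unclass(config),
    package_version = as.character(utils::packageVersion("reefmorph")))
  list(metrics = metrics, composition = composition, provenance = provenance)
}

# majority-vote block aggregation for categorical masks
resample_mask_majority <- function(mask, target_cell) {
  f <- target_cell / mask$cell_size
  if (abs(f - round(f)) > 1e-9)
    stop_invalid("mask cell size is not an integer divisor of the working grid")
  f <- as.integer(round(f))
  if (f == 1L) { mask$cell_size <- target_cell; return(mask) }
  m <- mask$labels
  nr <- nrow(m) %/% f; nc <- ncol(m) %/% f
  mm <- m[seq_len(nr * f), seq_len(nc * f), drop = FALSE]
  a <- array(mm, dim = c(f, nr, f, nc))
  out <- apply(a, c(2, 4), function(b) {
    b <- b[!is.na(b)]
    if (length(b) == 0) return(NA_integer_)
    as.integer(which.max(tabulate(b, 3)))
  })
  benthic_mask(out, cell_size = target_cell,
               origin = c(mask$origin[1],
                          mask$origin[2] + (nrow(m) - nr * f) * mask$cell_size))
}

#' Run the full multi-colony study
#'
#' Per-colony metrics and composition, a colony summary table (mean, SD,
#' median, min, max of GSD, planform area and the three category areas
#' across colonies), and -- given at least 6 colonies with masks -- the five
#' robust compositional regressions: fractal dimension, surface rugosity,
#' and the IQRs of slope, planform curvature and profile curvature, each
#' regressed on the zero-replaced, pivot-transformed composition by LTS.
#'
#' @param colonies a list of colonies, each a list with elements `dem`,
#'   `mask` (optional) and `colony_id` -- e.g. the output of [gen_study()].
#' @param config a [study_config()].
#' @return A list of class `reef_study`: `metrics`, `composition`,
#'   `summary`, `effects` (a `reef_effects` tibble with a `metric` column,
#'   or `NULL`), `config`.
#' @export
run_study <- function(colonies, config = study_config()) {
  if (length(colonies) == 0) stop_empty("no colonies supplied")
  ids <- vapply(seq_along(colonies), function(i) {
    id <- colonies[[i]]$colony_id
    if (is.null(id)) sprintf("colony_%02d", i) else as.character(id)
  }, "")
  if (anyDuplicated(ids)) stop_invalid("duplicate colony_id values")
  runs <- lapply(seq_along(colonies), function(i)
    run_colony(colonies[[i]]$dem, colonies[[i]]$mask, config, ids[i]))
  metrics <- dplyr::bind_rows(lapply(runs, `[[`, "metrics"))
  comps <- Filter(Negate(is.null), lapply(runs, `[[`, "composition"))
  composition <- if (length(comps)) dplyr::bind_rows(comps) else NULL

  summary_tbl <- NULL
  if (!is.null(composition)) {
    long <- tidyr::pivot_longer(
      dplyr::left_join(composition,
                       metrics[c("colony_id", "planform_area_m2")],
                       by = "colony_id"),
      cols = c("gsd_m", "planform_area_m2", "other_m2", "dead_m2", "live_m2"),
      names_to = "quantity", values_to = "value")
    summary_tbl <- dplyr::summarise(
      dplyr::group_by(long, .data$quantity),
      mean = mean(.data$value), sd = sd(.data$value),
      median = stats::median(.data$value),
      min = min(.data$value), max = max(.data$value), .groups = "drop")
  }

  effects <- NULL
  responses <- c("Fractal Dimension" = "fractal_d",
                 "Surface Rugosity" = "surface_rugosity",
                 "IQR Slope" = "slope_iqr",
                 "IQR Planform Curvature" = "plan_curv_iqr",
                 "IQR Profile Curvature" = "prof_curv_iqr")
  if (is.null(composition) || nrow(composition) < 6) {
    warn("fewer than 6 colonies with composition; regression stage skipped")
  } else {
    recs <- replace_rounded_zeros(composition, alpha = config$zero_alpha,
                                  mode = config$zero_mode)
    tabs <- list()
    for (nm in names(responses)) {
      yv <- metrics[[responses[[nm]]]][match(recs$colony_id, metrics$colony_id)]
      if (var(yv, na.rm = TRUE) == 0)
        warn(sprintf("%s is constant across colonies: degenerate design, effects reported as 0 with p = 1", nm))
      tabs[[nm]] <- tryCatch(
        coda_metric_regression(recs, yv, h = config$trim_h,
                               seed = config$seed),
        reefmorph_error = function(e) {
          warn(sprintf("regression for %s failed: %s", nm, conditionMessage(e)))
          NULL
        })
    }
    tabs <- Filter(Negate(is.null), tabs)
    if (length(tabs)) {
      effects <- effects_report(tabs)
      class(effects) <- c("reef_effects", class(effects))
    }
  }
  structure(list(metrics = metrics, composition = composition,
                 summary = summary_tbl, effects = effects, config = config),
            class = "reef_study")
}

#' @export
print.reef_study <- function(x, ...) {
  cat(sprintf("<reef_study> %d colonies\n", nrow(x$metrics)))
  if (!is.null(x$summary)) { cat("Summary:\n"); print(x$summary) }
  if (!is.null(x$effects)) { cat("Component effects:\n"); print(x$effects) }
  invisible(x)
}

#' Write the study's tables to CSV
#'
#' Emits `metrics.csv`, `composition.csv`, `summary.csv` and `effects.csv`
#' (those that exist) into `dir`. Deterministic: identical studies write
#' byte-identical files.
#'
#' @param study a `reef_study`.
#' @param dir output directory (created if missing).
#' @return Character vector of the files written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "reef_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in c("metrics", "composition", "summary", "effects")) {
    obj <- study[[nm]]
    if (is.null(obj)) next
    f <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tibble::as_tibble(obj), f)
    files <- c(files, f)
  }
  files
}

#' Plot component effects
#'
#' Bar chart of the predicted change in each structural metric per added
#' square metre of each benthic category, with SEM whiskers and significance
#' marks (`*` p < 0.05, `.` p < 0.10), one facet per metric.
#'
#' @param object a `reef_effects` tibble (with or without a `metric`
#'   column).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot reef_effects
#' @export
autoplot.reef_effects <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (!"metric" %in% names(df)) df$metric <- "effect"
  if (!"signif" %in% names(df))
    df$signif <- dplyr::case_when(is.na(df$p_value) ~ "",
                                  df$p_value < 0.05 ~ "*",
                                  df$p_value < 0.10 ~ ".", TRUE ~ "")
  df$part <- factor(df$part, benthic_categories())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$part, y = .data$delta_y_per_m2,
                                   fill = .data$part)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$delta_y_per_m2 - .data$sem,
                                        ymax = .data$delta_y_per_m2 + .data$sem),
                           width = 0.25) +
    ggplot2::geom_text(ggplot2::aes(label = .data$signif),
                       vjust = -0.5, size = 6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = expression(Delta * hat(y) / m^2)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write one effect figure per metric
#'
#' @param effects a `reef_effects` tibble with a `metric` column.
#' @param dir output directory.
#' @param device `"png"` or `"svg"` (passed to [ggplot2::ggsave()]).
#' @return Paths of the written figure files, one per metric.
#' @export
make_figures <- function(effects, dir, device = "png") {
  if (is.null(effects) || nrow(effects) == 0) stop_empty("no effects to plot")
  df <- tibble::as_tibble(effects)
  if (!"metric" %in% names(df)) df$metric <- "effect"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vapply(unique(df$metric), function(m) {
    p <- autoplot.reef_effects(df[df$metric == m, ])
    f <- file.path(dir, paste0(gsub("[^A-Za-z0-9]+", "_", tolower(m)), ".",
                               device))
    suppressMessages(ggplot2::ggsave(f, p, width = 5, height = 4, dpi = 150))
    f
  }, "")
}
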