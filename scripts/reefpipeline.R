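#!/usr/bin/env Rscript
# Thin command-line wrapper over the reefmorph package.
#
#   Rscript scripts/reefpipeline.R simulate --n 10 --seed 1 --out-dir sim/
#   Rscript scripts/reefpipeline.R metrics  --dem colony.asc [--mask mask.asc] --out metrics.csv
#   Rscript scripts/reefpipeline.R coda     --composition comp.csv --metrics metrics.csv --out effects.csv
#   Rscript scripts/reefpipeline.R run      --n 10 --seed 1 --out-dir study/ [--figures]
#
# Any command accepts --config <yaml> (see reefmorph::study_config()).

suppressMessages({
  library(optparse)
  library(reefmorph)
})

args <- commandArgs(trailingOnly = TRUE)
cmd <- if (length(args)) args[1] else ""
rest <- args[-1]

common <- list(
  make_option("--config", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = 1L)
)
get_config <- function(o) {
  cfg <- if (!is.null(o$config)) read_study_config(o$config) else study_config()
  cfg$seed <- o$seed
  cfg
}

if (cmd == "simulate") {
  o <- parse_args(OptionParser(option_list = c(common, list(
    make_option("--n", type = "integer", default = 10L),
    make_option("--out-dir", dest = "out_dir", type = "character",
                default = "simulated")))), args = rest)
  dir.create(o$out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- gen_study(n_colonies = o$n, seed = o$seed)
  for (col in st) {
    write_dem(col$dem, file.path(o$out_dir, paste0(col$colony_id, "_dem.asc")))
    write_mask(col$mask, file.path(o$out_dir, paste0(col$colony_id, "_mask.asc")))
  }
  cat(sprintf("wrote %d DEM/mask pairs to %s\n", o$n, o$out_dir))
} else if (cmd == "metrics") {
  o <- parse_args(OptionParser(option_list = c(common, list(
    make_option("--dem", type = "character"),
    make_option("--mask", type = "character", default = NULL),
    make_option("--id", type = "character", default = "colony"),
    make_option("--out", type = "character", default = "metrics.csv")))),
    args = rest)
  res <- run_colony(o$dem, o$mask, get_config(o), o$id)
  readr::write_csv(res$metrics, o$out)
  if (!is.null(res$composition))
    readr::write_csv(res$composition, sub("\\.csv$", "_composition.csv", o$out))
  cat(sprintf("wrote %s\n", o$out))
} else if (cmd == "coda") {
  o <- parse_args(OptionParser(option_list = c(common, list(
    make_option("--composition", type = "character"),
    make_option("--metrics", type = "character"),
    make_option("--response", type = "character", default = "fractal_d"),
    make_option("--out", type = "character", default = "effects.csv")))),
    args = rest)
  comp <- readr::read_csv(o$composition, show_col_types = FALSE)
  mets <- readr::read_csv(o$metrics, show_col_types = FALSE)
  cfg <- get_config(o)
  recs <- replace_rounded_zeros(comp, alpha = cfg$zero_alpha,
                                mode = cfg$zero_mode)
  y <- mets[[o$response]][match(recs$colony_id, mets$colony_id)]
  eff <- coda_metric_regression(recs, y, h = cfg$trim_h, seed = cfg$seed)
  effects_report(stats::setNames(list(eff), o$response), path = o$out)
  cat(sprintf("wrote %s\n", o$out))
} else if (cmd == "run") {
  o <- parse_args(OptionParser(option_list = c(common, list(
    make_option("--n", type = "integer", default = 10L),
    make_option("--in-dir", dest = "in_dir", type = "character", default = NULL),
    make_option("--out-dir", dest = "out_dir", type = "character",
                default = "study_out"),
    make_option("--figures", action = "store_true", default = FALSE)))),
    args = rest)
  cfg <- get_config(o)
  colonies <- if (!is.null(o$in_dir)) {
    dems <- sort(list.files(o$in_dir, "_dem\\.asc$", full.names = TRUE))
    lapply(dems, function(d) list(
      dem = d, mask = sub("_dem\\.asc$", "_mask.asc", d),
      colony_id = sub("_dem\\.asc$", "", basename(d))))
  } else gen_study(n_colonies = o$n, seed = o$seed)
  res <- run_study(colonies, cfg)
  files <- write_study(res, o$out_dir)
  if (o$figures && !is.null(res$effects))
    files <- c(files, make_figures(res$effects, file.path(o$out_dir, "figures")))
  cat(paste0("wrote:\n  ", paste(files, collapse = "\n  "), "\n"))
} else {
  cat("usage: reefpipeline.R simulate|metrics|coda|run [options]\n")
  quit(status = if (cmd == "") 0 else 1)
}
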