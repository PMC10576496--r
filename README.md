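# reefmorph

Colony-scale structural complexity of coral reefs, and its relation to
benthic composition.

Reef ecologists increasingly measure habitat structure from
photogrammetric digital elevation models (DEMs) of individual coral
colonies. A recurring question is how much of a colony's
three-dimensional complexity comes from live coral tissue versus dead
skeleton and other substrate. reefmorph implements the full desk-side
analysis for that question:

* **Terrain metrics** on square-celled elevation rasters: surface
  rugosity (3-D geodesic area / planform area), fractal dimension
  `D = 2 − slope[log S(δ) / log δ]` estimated from geodesic surface area
  across working resolutions of 1–32 cm (with an objective fractality
  check), and Zevenbergen–Thorne slope, planform curvature and profile
  curvature on 3×3 windows, summarized by mean/median/min/max/quartiles
  and IQR.
* **Benthic composition** from categorical masks (Live / Dead / Other):
  per-category planform areas with the detection limit set to one native
  pixel.
* **Compositional regression**: rounded-zero replacement
  (`α × detection limit`), pivot (ilr) log-ratio coordinates, and least
  trimmed squares (LTS) robust regression — exact by subset enumeration at
  study sizes, FAST-LTS beyond — reporting per category the predicted
  change in each structural metric per added m², `Δŷ/m²`, with SEM and
  p-value.
* **A seeded synthetic-data module** (fractional Brownian surfaces,
  smoothed categorical masks, Dirichlet compositions) so the whole
  pipeline is testable without field data.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` on effect tables.

## Worked example

Simulate one partially dead colony, run the metric battery, and quantify
its composition:

```r
library(reefmorph)

colony  <- gen_colony(colony_params(live_fraction = 0.4,
                                    dead_fraction = 0.45, seed = 7))
metrics <- colony_metrics(colony$dem, colony$mask,
                          config = study_config(), colony_id = "demo")
metrics[c("planform_area_m2", "surface_rugosity", "fractal_d",
          "slope_median", "prof_curv_iqr")]
#>   planform_area_m2 surface_rugosity fractal_d slope_median prof_curv_iqr
#> 1             2.56         3.002346  2.301913     50.17654      16610.56

quantify_areas(colony$mask, "demo", detection_limit_area = 1e-4)
#>   colony_id live_m2 dead_m2 other_m2 total_m2 detection_limit_m2
#> 1 demo         1.02    1.15    0.384     2.56             0.0001
```

The colony covers 2.56 m² of seafloor with three times that in draped
surface (rugosity 3.0), a fractal dimension of 2.30 over the 1–32 cm
range, and a median slope of 50° — values typical of branching coral
colonies. Its footprint is 1.02 m² live tissue, 1.15 m² dead skeleton and
0.38 m² other substrate.

A ten-colony study then asks how structure tracks composition:

```r
study <- gen_study(n_colonies = 10, seed = 1)   # Dead rougher than Live
res   <- run_study(study)
subset(res$effects, metric == "Fractal Dimension")
#>              metric  part delta_y_per_m2     sem  p_value signif
#> 1 Fractal Dimension  Live        -0.0619 0.00684 0.000180      *
#> 2 Fractal Dimension  Dead         0.0739 0.00924 0.000287      *
#> 3 Fractal Dimension Other        -0.0191 0.00924 0.118947
```

Each added square metre of live cover *lowers* the colony's fractal
dimension (−0.062 per m², p < 0.001) while dead skeleton raises it —
the generator builds Dead rougher than Live, and the regression recovers
that construction. `autoplot(res$effects)` draws the per-metric effect
bars with SEM whiskers and significance marks; `write_study(res, dir)`
emits the tables as CSV.

A thin command-line wrapper covers the same stages for shell use:

```sh
Rscript scripts/reefpipeline.R simulate --n 10 --seed 1 --out-dir sim/
Rscript scripts/reefpipeline.R run --n 10 --seed 1 --out-dir study_out/ --figures
```

## Documentation

The methods vignette (`vignettes/reefmorph-methods.Rmd`) documents the
models, the numerical conventions (edge trimming, quantile convention,
curvature scaling, zero replacement), the synthetic generator's design and
what it does and does not emulate, and known limitations.
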