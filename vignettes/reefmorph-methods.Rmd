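---
title: "Colony-scale structural complexity and compositional regression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colony-scale structural complexity and compositional regression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

reefmorph quantifies the three-dimensional structure of individual coral
colonies from photogrammetric digital elevation models (DEMs), and relates
that structure to the colony's benthic composition — how much of its
footprint is live coral tissue, dead coral skeleton, or other (mostly sandy)
substrate. This vignette is the package's account of its models, numerical
choices, and limitations. All quantities shown here are computed by the test
suite or the worked examples; nothing is quoted from elsewhere.

```{r setup, message = FALSE}
library(reefmorph)
```

## The analysis in one paragraph

Each colony contributes a DEM on a square 1 cm working grid and an aligned
categorical mask (Live / Dead / Other). From the DEM we compute five
structural metrics: surface rugosity, fractal dimension, and per-cell slope,
planform curvature and profile curvature (the last three summarized by their
interquartile range, IQR). From the mask we compute the planform area of
each category. Across colonies, each metric is regressed on the composition
using compositional data analysis: rounded zeros are replaced at a fraction
of the detection limit, the three-part composition is expressed in pivot
(ilr) log-ratio coordinates, and a least trimmed squares (LTS) robust
regression yields, per category, the predicted change in the metric per
additional square metre of that category.

## Terrain metrics

### Geodesic surface area and rugosity

The elevation lattice (cell centres as 3-D nodes) is triangulated: every
2×2 block of valid nodes contributes two triangles split along the NW–SE
diagonal. The raw triangle mesh spans only the $(n-1)\times(m-1)$
inter-node blocks, so boundary half-cells would be omitted and even a
perfectly flat raster would return less than its planform area. We therefore
apply an edge correction: the triangle sum is scaled by
(valid cells)/(complete valid blocks). With it,

* a horizontal plane returns its planform area to machine precision,
* a plane tilted at $\theta$ returns planform$/\cos\theta$ exactly
  (rugosity anchors $\sqrt 2$ at 45°, $2$ at 60°),
* rugosity $=$ geodesic / planform is $\ge 1$ with equality iff flat.

The tests cross-check the estimator against an independently coded
8-triangle (Jenness-style) per-cell fan, which agrees within 2 % on rough
fractional Brownian surfaces. The rugosity denominator is the planform
(map-projected) footprint: at colony extents of a couple of square metres
the distinction between a planar and an ellipsoidal reference surface is
many orders of magnitude below numerical precision.

### Fractal dimension from the multiscale area curve

Surface area is measured on a ladder of working resolutions
$\delta \in \{1, 2, 4, 8, 16, 32\}$ cm (block-mean aggregation by factors
1–32 on the 1 cm grid: the six steps double in linear resolution). The
fractal dimension is

$$D = 2 - \operatorname{slope}\left[\log S(\delta) / \log\delta\right],$$

with natural logarithms (the slope is base-invariant; the base is fixed for
bit-reproducibility). $D$ ranges from 2 (flat) to 3. Fractality — the
approximate linearity of the log–log relationship over the tested range —
is a prerequisite for a meaningful $D$; the package makes the usual visual
check objective as `is_fractal = (R² ≥ 0.98)`, reporting $D$ regardless
with the flag marking unreliable cases. A zero-variance (flat) curve is a
perfect fit by convention, so a flat DEM gives exactly $D = 2$,
`is_fractal = TRUE`.

**Edge trimming.** Before any metric, the raster is trimmed at the coarsest
aggregation factor: the grid is divided into 32×32-cell blocks and any
block touching no-data (outside the model boundary) is dropped at the
original resolution. This one-time trim makes the valid footprint an exact
union of coarsest-factor blocks, so every rung of the $S(\delta)$ ladder
sees the *identical* footprint. Without it the footprint would shrink at
coarse factors, which tilts the log–log slope: on irregular grids a flat
surface would not return $D = 2$.

**Scaling regime.** An area-based estimator reads the self-affine exponent
only where local gradients are steep ($\sec\theta \approx |\nabla z|$);
where a surface is nearly level the area barely exceeds planform at any
resolution and the estimator returns $D \to 2$ regardless of the true
exponent. Coral colonies, with median slopes of roughly 40–60°, are in the
informative regime; the package's fBm recovery tests use amplitudes chosen
(by the gradient analysis $g(\delta)\approx\sigma(\delta/L)^H/\delta$) to
keep all six scales steep. Users applying the estimator to near-flat
surfaces should treat small $D$ as a floor, not an estimate.

### Slope and curvature

Slope and the two curvatures come from the Zevenbergen–Thorne nine-term
surface fitted to each interior cell's 3×3 window (border cells and cells
whose window touches no-data are no-data):

* slope $= \arctan\sqrt{G^2 + H^2}$ in degrees, with $G, H$ the east–west
  and north–south gradients over $2\,\times$ cell size;
* profile curvature $= -2(DG^2 + EH^2 + FGH)/(G^2+H^2)\times 100$
  (positive = convex-upslope);
* planform curvature $= 2(DH^2 + EG^2 - FGH)/(G^2+H^2)\times 100$.

The ×100 scaling is the conventional terrain-curvature reporting scale.
Cells with a vanishing gradient ($G^2 + H^2 < 10^{-12}$, i.e. gradients
below $10^{-6}$) take curvature 0 rather than no-data: this keeps
dispersion summaries defined on near-planar sandy substrate, where the
analysis needs them. An Evans-style full least-squares quadratic is
available behind `study_config(curvature_method = "evans")`. Both
implementations are verified cell-for-cell (to $10^{-9}$) against a
brute-force looped implementation, and against closed forms on planes and
parabolic sheets.

Summaries (mean, median, min, max, quartiles, IQR) use R's default
linear-interpolation quantile convention (type 7), fixed so IQRs are
reproducible. The IQR is the headline dispersion summary: at colony scale,
means flatten the highly variable relief that the analysis is after.

## Compositional regression

### Rounded zeros

A category absent from a mask is recorded as 0 m² — a *rounded* zero,
below the detection limit rather than structurally impossible. The
detection limit is the area of one native pixel (ground sampling distance
squared; native GSD is carried as provenance through resampling). Each zero
part is replaced by $\alpha\,\times$ detection limit with $\alpha = 0.05$.
The default `simple_substitution` leaves nonzero parts untouched, because
the compositions here are *not* closed — total colony areas vary freely. A
`closed_multiplicative` mode that rescales nonzero parts to preserve each
record's total is provided for closed data.

### Pivot coordinates and per-part effects

With parts $(x_j, x_k, x_l)$ all positive, the pivot coordinates for pivot
$j$ are

$$z_1 = \sqrt{2/3}\,\ln\frac{x_j}{\sqrt{x_k x_l}},\qquad
  z_2 = \sqrt{1/2}\,\ln\frac{x_k}{x_l},$$

with $(k, l)$ the remaining parts in the fixed order Live, Dead, Other.
They are scale-invariant, so raw areas and closed proportions give the same
coordinates. Each part takes the pivot role in turn; the three fits are
rotations of one coordinate system and share fitted values, residuals, and
LTS objective (asserted in the tests to $10^{-9}$; the fast LTS search uses
the same elemental-start seed in each rotation, which makes the equality
exact rather than approximate).

The reported `delta_y_per_m2` converts the $z_1$ coefficient to a practical
scale by a finite-difference prediction at the part-wise mean composition:
$\hat y(\bar x + 1\,\mathrm{m^2}\,e_j) - \hat y(\bar x)$, i.e. the
predicted change in the metric when one square metre of category $j$ is
added and the other two areas are held fixed. This is one of several
defensible conversions (a linearization at $\bar x$ is another); the raw
coordinate coefficient is always reported alongside so the conversion can
be redone under a different convention. Magnitudes of converted effects
should not be compared across conventions.

### Least trimmed squares

LTS minimizes the sum of the $h$ smallest squared residuals; the default
$h = \lfloor (n+p+1)/2 \rfloor$ gives maximum breakdown. For $n \le 15$
the fit is exact, by exhaustive enumeration of h-subsets (each subset's own
OLS evaluated on that subset) — at the study scale of ~10 colonies every
regression is exact. Larger problems use the FAST-LTS concentration
scheme: 500 seeded random $(p{+}1)$-point elemental starts, two
concentration steps each, and full convergence iterations from the ten best
candidates. The tests require the fast objective to equal exhaustive
enumeration on 20 seeded problems, and never to exceed the criterion of an
independent LTS implementation.

Inference uses the standard reweighting: residuals are scaled by the
consistency-corrected LTS scale
$\hat\sigma = \sqrt{\text{obj}/h}\,/\,\sqrt{1 - 2q\varphi(q)/a}$ (with
$a = h/n$, $q = \Phi^{-1}((1+a)/2)$), observations with
$|r|/\hat\sigma \le 2.5$ get weight 1, and classical weighted-OLS standard
errors and t-based p-values follow. At $n = 10$ these p-values rest on few
effective observations and should be read qualitatively — the same caveat
applies to any robust fit at this sample size.

Significance marks in reports and figures: `*` for $p < 0.05$, `.` for
$p < 0.10$.

## The synthetic-data generator

No field DEMs ship with the package; a seeded generator supplies inputs
with the statistical structure the analysis assumes.

**Surfaces.** Fractional Brownian surfaces are synthesized spectrally:
white Gaussian noise filtered so the power spectral density falls as
$f^{-(2H+2)}$, then rescaled so the elevation SD equals the requested
amplitude exactly. Theoretical fractal dimension is $3 - H$. Spectral
synthesis (over midpoint displacement) gives exact control of the power-law
exponent at the cost of one FFT.

**Colonies.** A colony composites three category surfaces through a
simulated mask. Critically, the Live and Dead fields are driven by *one*
white-noise spectrum — identical phases, different spectral decay — so
Live is literally a smoothed rendering of the same underlying skeleton.
With independent fields, category boundaries would be artificial cliffs
that make mixtures rougher than either pure category and destroy the
monotone relation between composition and colony roughness; with shared
phases the boundaries are continuous at coarse scales. Other substrate is
millimetre-scale Gaussian texture about a base plane (sand). Defaults
(`hurst` 0.8 live / 0.45 dead, amplitudes 0.10 / 0.18 m, 2 mm sand
texture) put whole-colony metrics in the ranges reported for shallow
*Acropora* colonies — $D$ about 2.2–2.4, rugosity about 2–4, median slope
about 30–70° — with Dead rougher than Live. The live/dead roughness
*contrast* is calibrated only to reproduce that ordering; its magnitude is
a free choice, since only category-mean summaries of real colonies are
available to compare against.

**Masks.** Categories are assigned by ranking a smoothed Gaussian field and
cutting at the requested fractions, so realized fractions are exact to one
cell and categories form contiguous blobs (the smoothing kernel scale is
three times the `smoothness` parameter; at the default this keeps each
category in at most a handful of connected components on a 256² grid).

**Studies.** `gen_study()` sweeps the live fraction across colonies while
drawing the Other fraction independently per colony from U(0.05, 0.35).
The independent variation matters: with Other held fixed, the two pivot
coordinates become nearly collinear and the per-part effects are
sign-unstable — real surveys show Other cover ranging from nearly zero to
dominant, and the generator reproduces that spread. Each colony gets an
irregular survey footprint built as a connected union of 12–24
coarsest-factor blocks (0.1024 m² each), spanning planform areas of about
1.2–2.5 m²; footprints are block-aligned so the edge trim is a no-op on
them.

**Determinism.** Every generator derives its random stream from the user
seed by a fixed offset, restores the caller's RNG state, and returns
bit-identical output for identical arguments; adding a generator never
perturbs another's draws.

**What the generator does not emulate.** Real photogrammetric DEMs have
reconstruction noise, occlusions and holes, depth-dependent accuracy, and
overhangs collapsed by the planar viewing geometry; coral skeleta are not
Gaussian self-affine fields, and live-tissue smoothing is not a pure
spectral filter. Passing tests on synthetic colonies show the *pipeline*
is correct and that its statistical stage recovers known structure; they do
not certify effect magnitudes on field data.

## Problem sizes and numerical choices

The shipped tests run on 64²–512² grids, 5–20 seeds per stochastic check,
200 replicates for coefficient recovery at $n = 50$, and 20 simulated
10-colony studies for the end-to-end sign check — sizes chosen so the full
suite completes in about two minutes on one core while leaving Monte-Carlo
error well below the tolerances tested. Other conventions, fixed once:

* grid indices are 0-based row-major from the top-left (row 1 = north);
  the geotransform origin is the lower-left corner;
* block-mean (not bilinear) resampling — the metrics are area-based and
  block means preserve integrated elevation;
* a block containing any no-data cell resamples to no-data (conservative);
* the polygonize-then-clip edge trim is realized as a block-membership
  test, equivalent on axis-aligned grids;
* GeoJSON polygon masks rasterize by cell-centre membership (even–odd
  rule), ties to the first-listed polygon, mirroring digitization order;
* DEMs and masks travel as ESRI ASCII grids (plain text, lossless to 15
  significant digits); mask codes are 1 = Live, 2 = Dead, 3 = Other,
  0 = no-data.

## Known limitations

* Planar-view DEMs ignore undersides and overhangs; all metrics describe
  the top surface only.
* The $S(\delta)$ estimator saturates at $D \approx 2$ on low-gradient
  surfaces (see the scaling-regime note); $D$ comparisons are meaningful
  only within a common gradient regime.
* Category-restricted metrics (e.g. Live-only $D$) use per-factor clipping
  of blob-shaped regions, so their footprints differ across resolutions;
  they are comparable between categories of the same colony, but are noisier
  than whole-colony metrics and occasionally undefined for sparse
  categories (reported as `NA` with a warning).
* p-values at $n \sim 10$ from reweighted LTS are fragile; reports carry
  the effective sample size via `glance()`.
* No multiple-testing correction is applied across the five metrics, by
  design: the analysis reports per-metric tables.
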