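---
title: "Evaluating regular sampling designs on elevation-like surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating regular sampling designs on elevation-like surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridrep)
library(dplyr)
set.seed(1)
```

## The question

Ecological surveys almost never observe a landscape exhaustively: they place
a handful of plots and hope the plots stand for the whole. `gridrep` asks,
quantitatively, when that hope is justified for regular (evenly spaced)
designs at the meso scale (1–100 km). It treats a full-resolution elevation
raster as the *population*, draws regular samples of increasing size from
it, interpolates a surface back from each sample, and scores both the
sample and the interpolation against the population. Elevation is the test
variable because it is measured everywhere (so the truth is known), varies
smoothly in space like many ecological covariates, and its within-area
standard deviation is a natural one-number summary of landscape
heterogeneity.

Three complementary metrics are used:

* **Representativeness** — the two-sample Kolmogorov–Smirnov comparison of
  the sample's (or interpolation's) value distribution against all raster
  cells. Higher p means the two distributions are harder to distinguish.
* **Similarity** — Pearson correlation between interpolated and true cell
  values (interpolations only, where a cell-wise pairing exists).
* **Accuracy** — cell-wise RMSE in meters (interpolations only).

Trends of each metric over sample size *n* and area SD are summarized with
penalized-spline additive models, and break-points ("how large must *n* be
before the metric stabilizes?") are located with a conditional-inference
partitioner.

## The synthetic terrain generator

Real 90 m digital-elevation tiles are the natural population surface, but
the pipeline must run from scratch, so `make_gaussian_field()` simulates
5 × 5 km tiles with the same coarse statistical structure:

1. white Gaussian noise on the 56 × 56 grid is convolved (FFT, on the
   torus) with an isotropic Gaussian kernel whose width is set by
   `correlation_length`;
2. the field is standardized and, for `tail = "long_tailed"`, passed
   through `exp()` — a monotone convex transform that forces the right
   skew seen in dissected terrain with incised drainages;
3. the result is affinely rescaled so the realized raster mean and SD equal
   the targets exactly.

Defaults encode the study conditions the package emulates: 5 × 5 km at 90 m
resolution; mean elevation 159.5 m (the Amazon-wide mean for such tiles);
SD defaulting to 40 m, the value below which ~90% of 5 × 5 km Amazonian
areas fall; experiments draw per-area SD uniformly from 1–56 m, bracketing
that band. The `correlation_length` default of 1000 m makes terrain vary
smoothly at the between-plot distance (1 km), which is the regime where
sparse regular sampling is a sensible design at all; fields much rougher
than the plot spacing cannot be represented by any 30-plot design.

What the generator does **not** emulate: landforms (ridgelines, valley
networks, terraces), anisotropy, and the site-specific marginal shapes of
real tiles. Passing tests therefore demonstrate that the *pipeline*
behaves correctly and that its qualitative conclusions hold on smooth
heterogeneous surfaces — they do not certify any particular real landscape.
Real rasters can be substituted directly via `read_raster()` (ESRI ASCII or
single-band TIFF).

```{r terrain}
r <- make_gaussian_field(terrain_spec(target_sd = 30, seed = 42))
r
```

## Sample designs

`regular_lattice(raster, n)` places *n* points on the most-nearly-square
factor-pair lattice spanning the extent, then shifts the whole lattice by
one uniform random offset (up to half a spacing in each axis), wrapping
torus-fashion back into the extent. The wrap keeps the point count and
spacing exact in every iteration while varying the anchoring — the
"starting point" that differs between realizations of a survey. The offset
distribution is a design choice (the field protocol it mimics only says
that starting points differ); the torus wrap was chosen because it
preserves exact *n* and spacing, at the price of occasionally splitting the
lattice across the extent boundary.

`rapeld_design()` reproduces the standard 25 km² trail-grid survey layout:
six parallel 5 km trails 1 km apart, five plots per trail at 1 km
intervals, 30 plots. Some real grids carry a 31st plot; the generator fixes
30, and custom plot lists can be supplied as CSV (`read_design()`).

Values are extracted at the nearest cell center with no smoothing, so a
sample is a true subset of population values and the KS comparison is a
genuine sample-versus-population test.

## Interpolation

Inverse-distance weighting with `power = 2` and a global neighborhood is
the default (`idw_config()`). IDW was chosen because it remains usable at
the smallest sizes evaluated (n = 4), where variogram-based kriging is not
estimable. The exponent and neighborhood are exposed because field tools
differ; predictions are convex combinations of sample values, exact at
sample locations, and evaluated at every population cell center so the
interpolated surface can be scored cell-wise.

## Metrics: numerical choices

* KS D is computed exactly by a sweep over the pooled sorted values, which
  is correct under ties (elevation grids are full of ties).
* The KS p-value uses the asymptotic Kolmogorov distribution at
  `sqrt(n_eff) * D`; the population side here is thousands of cells, the
  regime where the asymptotic form is standard. It is a representativeness
  *score*, monotone in D at fixed sizes, not a calibrated hypothesis test.
* A correlation with a zero-variance side is reported as `NA`
  ("undefined"), never coerced to 0, and such rows are dropped listwise
  from trend fits — otherwise perfectly interpolated constant areas would
  register as maximally dissimilar.
* RMSE is defined only for interpolations: samples and population differ in
  length, so no cell-wise pairing exists.

```{r metrics}
design <- regular_lattice(r, 30)
sv <- extract_values(r, design)
surface <- idw_grid(sv, r)
bind_rows(score(sv, r, sample_size = 30), score(surface, r, sample_size = 30))
```

## Trend smooths

`fit_smooth()` fits `y ~ s(sample_size) + s(sd)` with penalized regression
splines, smoothing parameter by generalized cross-validation, via mgcv —
the standard tool for penalized additive models, and deliberately additive
univariate smooths rather than a bivariate surface (the simplest model
that answers "how does each driver act?"; an interaction would not be
identifiable from 6 sample sizes anyway). The basis dimension adapts to
the number of distinct covariate values because `sample_size` takes only
six. Deviance explained is `1 - RSS/TSS` for this Gaussian case. Fitted
trends carry pointwise `fit ± 1.96·SE` bands.

## Break-point trees

`fit_ctree()` implements conditional-inference recursive partitioning with
Monte-Carlo permutation tests: at each node the association of each
covariate with the response is scored by the absolute centered linear
statistic, its p-value estimated from (default) 9,999 index permutations
with the plus-one correction, Bonferroni-adjusted across covariates.
Splitting stops when no adjusted p falls below `alpha = 0.05` or a child
would drop below `min_node = 20` rows. The cutpoint maximizes
`|mean_L - mean_R| * sqrt(n_L n_R / n)` over midpoints between distinct
sorted values, ties to the lower cutpoint.

Monte-Carlo permutation was preferred over the asymptotic conditional
distributions of the classical formulation because it is exact at small
node sizes and reproducible under a seed; permuting *indices* makes the
p-values invariant to affine transforms of the response. Standardizing the
linear statistic (as the asymptotic theory does) is a monotone rescaling
under permutation, so it is omitted. Calibration was verified by
simulation: on independent-noise responses the fitted tree is a single
leaf in ~95% of runs at `alpha = 0.05`, matching the nominal level, and on
step responses the first split recovers the generating covariate and gap.

## The experiment harness

`run_experiment()` draws `n_areas` synthetic tiles (per-area SD uniform in
`sd_range`), evaluates every (size, iteration) with a fresh lattice offset,
averages metrics over iterations within each (area, size, source) cell,
and fits the four standard trend models on the means: sample KS-p,
interpolation KS-p, interpolation r, interpolation RMSE, each against
sample size and SD. Per-area seeds derive from `master_seed` by a fixed
multiplicative counter, so runs are bit-reproducible end to end and any
area can be regenerated in isolation. Failed areas are warned about,
skipped and counted — they do not silently bias means.

The standard problem size (50 areas × 6 sizes × 10 iterations on 56 × 56
tiles, 999 permutations) was chosen so a full run completes in about 1–2
minutes on one core while leaving per-size means stable to a few percent;
the tests and `scripts/acceptance.R` run exactly this configuration.

```{r experiment, eval = FALSE}
cfg <- experiment_config(n_areas = 50, master_seed = 1)
e <- run_experiment(cfg)
e
autoplot(e, "rmse")
```

## Known limitations

* Synthetic tiles are stationary and isotropic; real terrain has gradients
  and directionality, which are known to degrade regular designs further.
  Conclusions about required sample sizes transfer to real rasters only as
  far as those rasters resemble smooth correlated fields.
* The interpolation-side KS p-value compares two full grids (thousands of
  cells each), so even small distributional distortions from IDW smoothing
  are "significant"; it is best read comparatively across sizes, not
  against 0.05.
* Field workflows rarely record their IDW exponent and neighborhood;
  power 2 with all samples is the dominant default of common GIS tooling,
  and both are configurable here.
* Stratified, random and clustered designs are out of scope; only regular
  lattices, the trail-grid layout, and user-supplied point lists are
  evaluated.
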