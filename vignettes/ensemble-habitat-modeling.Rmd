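---
title: "Ensemble habitat suitability modeling for deep-sea benthos: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble habitat suitability modeling for deep-sea benthos: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benthosdm)
```

## The modeling problem

Deep-water corals and sponges are recorded almost exclusively as
presence-only observations: expeditions note where an organism was seen, but
the absence of a record says more about where ships and cameras went than
about where the organism is missing. `benthosdm` implements the standard
presence–background strategy for this situation. Presences for a taxon are
contrasted against a large set of *pseudoabsences* — background points that
deliberately carry the **same spatial sampling bias** as the presences — so
that the contrast between the two groups reflects environmental preference
rather than survey effort. The workflow is:

1. derive terrain predictors from bathymetry (slope, aspect indices,
   curvatures, surface-ratio roughness, multi-scale TPI, multi-scale VRM);
2. approximate near-bottom conditions by *upscaling* coarse depth-layered
   oceanographic fields to the bathymetric depth of each fine grid cell;
3. screen predictors for collinearity (Pearson |r| > 0.7) with a
   priority-driven greedy rule and a supporting cluster dendrogram;
4. estimate survey effort as a 2-D Gaussian kernel density (KDE) of the
   presence locations and sample 10,000 pseudoabsences from it;
5. fit four presence–background learners — boosted regression trees (BRT),
   a binomial additive model (GAM), a maximum-entropy model (Maxent), and a
   random forest (RF) — and combine them into an AUC-weighted ensemble;
6. evaluate by Monte-Carlo cross-validation (AUC, TSS), map per-cell
   prediction uncertainty, and summarize highly suitable habitat (> 0.7) by
   geomorphic class.

Because real occurrence databases and oceanographic archives cannot be bundled
or re-downloaded reproducibly, the package also ships a synthetic seascape
generator with *known* niches, and the entire pipeline is validated by
recovering those known truths.

## Data model and conventions

Rasters are `bgrid` objects: a numeric matrix on an unprojected geographic
grid, indexed row-major from the north-west corner, with **cell-center**
origin coordinates and NA as nodata. All stages propagate nodata: a cell
masked in any input is masked in the output, and focal operations return
nodata where their window is incomplete rather than padding beyond the grid.
Computation is in double precision; file round-trips promise single-precision
fidelity. Raster I/O uses the plain-text ESRI ASCII grid format, which
carries the same geotransform and nodata metadata as a single-band GeoTIFF;
depth-layered fields use a documented plain-text serialization
(`write_layered_field()`).

Metric distances on the geographic grid use a constant 111.195 km/degree
meridionally and a per-row `cos(latitude)` factor zonally. Within a focal
window the zonal spacing of the window's center row is used throughout; for
the ~1 km cells and ≤ 50 km windows involved, the within-window latitude
correction this ignores is far below the other approximations in play.

## Terrain metrics

*Slope* uses the 4-cell (rook neighbors) central-difference gradient, in
degrees. *Aspect* is reported as eastness = sin(aspect) and
northness = cos(aspect) of the downslope direction; flat cells have no
aspect and are masked. *Curvatures* come from the 6-parameter quadratic
surface fit to each 3×3 window (Evans method), signed so that convex
features are positive; the longitudinal (along-slope) and cross-sectional
(across-slope) components always sum to the general curvature, and on flat
cells where the slope direction is undefined each takes half the general
value. *Roughness* is the ratio of triangulated surface area (eight
triangles from the cell center to the midpoints toward its eight neighbors,
whose footprints tile exactly one cell) to planimetric area, ≥ 1 by
construction. *TPI* at radius r is the cell's elevation minus the mean over
all cells whose centers lie within r (full disk, center excluded) — positive
on summits and ridges; the conventional analysis scales are 1–50 km. *VRM*
follows the two-step construction: per-cell unit normals from 3×3
slope/aspect, then 1 − |resultant|/n² over an n×n window (n odd, 3–21),
which measures terrain heterogeneity independently of steepness — a
uniformly tilted plane scores 0.

Every metric is checked against an independent per-cell brute-force oracle
(scalar loops, `lm()` quadratic fits, Heron-formula triangle areas) to 1e-8
on batteries of random grids, and against exact analytic cases (flat plane,
45° plane, paraboloid dome).

## Seafloor upscaling

Coarse climatological fields are 3-D arrays over depth levels. For each fine
bathymetry cell the package interpolates each depth level horizontally
(bilinear) to the cell center and then linearly in depth to the cell's
seafloor depth, clamping beyond the first/last level. Linear vertical
interpolation between bracketing levels is the simplest defensible choice
and is tested to be *exact* for depth-linear, horizontally constant fields,
and against a hand-computed 2×2×2 toy to 1e-12.

## Survey-effort KDE and pseudoabsences

The effort surface is a product-Gaussian KDE of presence coordinates in
degrees, evaluated at every unmasked cell center and normalized to sum to 1.
The bandwidth defaults to Scott's normal-reference rule per axis
(`sd · n^(-1/6)`); the study this design follows did not state a bandwidth,
so a standard, reproducible default is used and is overridable. Whether to
compute the KDE in degrees or projected distances was also unstated;
degrees with per-axis bandwidths is adopted. Pseudoabsences are drawn
cell-wise with replacement, with probability proportional to effort, and
recorded at cell centers; cells holding presences are excluded by default
(pseudoabsences stand in for absences). Draws at n = 10^5 pass a chi-square
goodness-of-fit test against the surface.

The design matrix attaches prevalence weights that equalize total class
weight (each class carries half), because a few hundred presences against
10,000 pseudoabsences would otherwise dominate every loss function; the R
packages conventionally used for this kind of analysis apply the same
correction internally. Deduplication is exact-coordinate, matching how
presence-only archives are cleaned.

## The four learners

All learners predict a habitat suitability score in [0, 1].

* **BRT** — gradient boosting with Bernoulli (logistic) loss, tree
  complexity (depth) 3, and at least 1,000 trees. The learning rate is not
  part of the published configuration; the package fixes 0.01 and trains
  exactly the requested number of rounds, so the 1,000-tree floor holds by
  construction.
* **GAM** — binomial additive model with one thin-plate regression spline
  per predictor at basis dimension 12 (penalized by REML, so effective
  degrees of freedom ≤ 12). Predictors with too few distinct values fall
  back to linear terms.
* **Maxent** — authored in-package through the penalized-logistic (Gibbs)
  equivalence of maximum-entropy density estimation: linear, quadratic and
  hinge features (10 forward + 10 reverse knots per variable) built on the
  training range, per-feature L1 penalties following the original
  software's defaults (class base interpolated on the number of presences,
  scaled by the feature's spread over presences, hinge base 0.5), all
  multiplied by the regularization multiplier β (default 5). Coordinate
  descent (glmnet) solves the weighted problem (background weight 100);
  predictions use the complementary log-log transform of the normalized
  exponential model. Larger β demonstrably shrinks coefficients toward a
  constant-prevalence model.
* **RF** — 501 probability trees, depth capped at 10,
  mtry = ⌊√p⌋, class-balanced by the design-matrix weights; suitability is
  the fraction of trees voting presence.

The **ensemble** is the AUC-weighted average: w_i = AUC_i / ΣAUC, a convex
combination bounded cell-wise by the member minimum and maximum. Weights are
based on training-data AUC (test-based weighting is available via the CV
report); raw AUC rather than AUC − 0.5 is used, since the source analysis
states only that weights were based on AUC scores.

## Evaluation

AUC is computed as the Mann–Whitney rank-sum probability with ties counted
half, and equals exhaustive pair counting. TSS(t) = sensitivity +
specificity − 1; the default policy scans all candidate thresholds
(midpoints between distinct scores) and reports the maximum, the convention
of the packages this analysis style comes from. Cross-validation is k = 10
*Monte-Carlo* 80/20 resamples — independent random partitions with
replacement between runs, not disjoint folds — withholding 20% of presences
and of pseudoabsences each run; the final model is refit on all data.
Uncertainty maps are the per-cell standard deviation of suitability across
the k resampled refits. Variable contributions are permutation importances
(mean drop in correlation between original and permuted-variable
predictions, rescaled to percentages summing to 100) — the convention of
ensemble-modeling toolkits, since the originating analysis did not state its
internal method. Response curves are evaluation strips: one variable swept
across its observed range with the others held at their training medians
(medians, not means, to resist skew; the construction was not stated in the
source and is flagged as a package choice).

## The synthetic seascape and what passing tests mean

`make_bathymetry()` builds an abyssal plain (spatially correlated noise from
separable Gaussian smoothing of white noise) studded with Gaussian seamounts
of randomized height, radius, eccentricity and orientation (a fraction
flat-topped), on a 0.0083° grid. The default benchmark seascape
(120×120 cells, 12 seamounts of 2–6 km radius over a −4500 m plain) puts
large terrain features over roughly a percent of the seascape, mirroring
study regions where seamounts cover a few percent of a vast abyssal domain
and suitable habitat is confined to small pockets. `make_env_fields()`
produces depth-covarying layers (silicate, dissolved oxygen, POC flux,
aragonite saturation by default) as profile(depth) + correlated noise, with
noise levels set so the layers correlate only moderately (|r| well under the
0.7 screen), as a post-screening predictor set would; it also emits a coarse
depth-layered 3-D field whose exact seafloor evaluation is known, for
upscaling tests. `simulate_species()` plants a known niche (Gaussian,
logistic, or threshold-linear responses, multiplied across variables) and
samples presences by thinning an effort-proportional point process —
candidate cells drawn from the effort surface, accepted with probability
equal to true suitability — capped at exactly n presences.

The headline check, `niche_recovery_benchmark()`, simulates a species with a
single-variable Gaussian niche (silicate optimum 60, width 8) under two
broad survey-effort hotspots, 200 presences, and the full study
configuration (10,000 bias-matched pseudoabsences, all four learners at the
hyperparameters above, 10×80/20 Monte-Carlo CV). Passing means: every
learner and the ensemble exceed 0.9 mean held-out AUC, the ensemble response
curve peaks within 10% of the variable's range of the true optimum, and the
niche variable receives the largest permutation contribution. Note what this
does and does not establish: the synthetic fields are smooth, the niche is
low-dimensional and noise-free given the layers, and detection within
surveyed cells is perfect — so success demonstrates the machinery is
correct and the bias correction works as designed, not that comparable
accuracy would be achieved on real, messier occurrence data. The ceiling on
held-out AUC in this design is set by niche–effort overlap: pseudoabsences
that land on genuinely suitable cells are indistinguishable from presences
in environmental space, so as survey effort concentrates on suitable
terrain, attainable AUC falls — the reason bias-matched designs favor large
background samples over vast, mostly unsuitable study areas.

## Numerical choices and degenerate inputs

Problem sizes in the tests and acceptance script (grids of 10–120 cells per
side, 200 presences, 10,000 pseudoabsences, k = 10) are chosen so the whole
suite runs in minutes on a single core while keeping every contract
non-trivial. Other fixed choices: flat cells get VRM normal (0, 0, 1) and no
aspect; TSS threshold candidates include one below the minimum score (the
all-presence classification); CV splits that would lose a class are
impossible under stratified resampling, so no retry loop is needed; KDE
normalization fails loudly if all mass falls on masked cells; pseudoabsence
sampling fails loudly if exclusion removes all probability mass; the
suitability product is rescaled by its maximum so every simulated species
has a usable dynamic range; screening is deterministic given the priority
order, and expert judgment (e.g. retaining a biologically important variable
despite moderate correlation) enters only through that order.

## Known limitations

Geographic grids only (no projections); no spatially blocked CV, so
evaluation can be optimistic under strong spatial autocorrelation; Maxent
uses linear/quadratic/hinge features (no product or threshold features); the
ensemble weights are not recalibrated per cell; the synthetic generator does
not attempt oceanographic realism (no circulation, dispersal, or temporal
dynamics).
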