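---
title: "Methods: land-cover change, fragmentation and transition risk in forestdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: land-cover change, fragmentation and transition risk in forestdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

forestdyn analyses pairs of co-registered categorical land-cover rasters
(30 m cells, row 1 = north, cell-centre coordinates) under a 15-class
montane scheme: alpine vegetation (> 3,000 m), fir/rhododendron
(> 2,500 m), three closed-canopy forest bands (> 1,800 m, 600–1,800 m,
< 600 m), two secondary-forest bands, shrub/bush, four human-impact
classes, and rock, snow and water. For change analysis the classes
aggregate to five categories — alpine, forest, shrubland,
agriculture/developed and *other* — where *other* collects the
non-vegetated classes so that all 15 classes stay in the accounting even
though only the vegetated categories are modelled.

Elevation bands are half-open and lower-inclusive: [min, 600), [600,
1800), [1800, 2500), [2500, 3000), [3000, ∞). Published class
descriptions say "between" without boundary rules; lower-inclusive
intervals were chosen once for determinism and used everywhere (band
assignment, reassignment, the generator).

Rasters travel as ESRI ASCII grids and polygons as GeoJSON. GeoTIFF was
not used because no R GeoTIFF reader is available in the deployment
environment; the ASCII grid is a standard, lossless, plain-text
single-band raster format and the package's own reader/writer round-trips
values, nodata and the affine georeference exactly.

# Classification stage

The classifier is a random forest with the study-design parameters: 500
trees, 2/3 of the training data drawn *with replacement* per tree,
`floor(sqrt(p))` candidate predictors per split, majority vote. It is
implemented in compiled code inside the package (CART with Gini impurity);
vote ties resolve to the smallest class index, and R's RNG drives all
sampling so `set.seed()` gives identical maps. Training pixels are drawn
without replacement, at most 30 per polygon.

Post-processing follows the sentence order of the study design: gap fill →
elevation-band reassignment → majority filter.

* `fill_gaps()` only ever writes into nodata cells of the primary map.
* `reassign_elevation_band()` relabels pixels of the four forest-band
  classes (fir/rhododendron participates as the ≥ 2,500 m band) to the
  class of their DEM band; non-forest classes are untouched. The operation
  is idempotent.
* `majority_filter()` replaces each valid cell by the modal class of its
  3×3 neighbourhood (nodata excluded from the vote, truncated windows at
  borders, single pass). Tie rule, unspecified in the study design and
  chosen here for determinism with minimal bias: if the centre's own class
  is among the tied maxima the centre is retained, otherwise the smallest
  code wins. Nodata centres stay nodata — inventing data is the gap
  filler's job, not the filter's.

# Accuracy and error-adjusted areas

`olofsson_estimates()` implements the stratified good-practice estimators.
Strata follow the *mapped* classes of the assessed map, so the weights
come from mapped areas (the per-class validation-polygon design implies
map-class stratification). With weights $W_i$ and row totals $n_{i+}$:

$$\hat p_{ij} = W_i\,n_{ij}/n_{i+},\qquad
  \mathrm{OA} = \sum_i \hat p_{ii},\qquad
  \hat A_j = A_\mathrm{tot}\sum_i \hat p_{ij},$$
$$\mathrm{SE}(\hat A_j) = A_\mathrm{tot}
  \sqrt{\sum_i W_i^2\,\frac{\tfrac{n_{ij}}{n_{i+}}
  \bigl(1-\tfrac{n_{ij}}{n_{i+}}\bigr)}{n_{i+}-1}},$$

with 95 % CIs at $1.96\,\mathrm{SE}$ (normal approximation, matching the
"95 % CI" convention of the reference tables). Adjusted areas sum exactly
to the total mapped area for any valid matrix. Classes absent from the map
($W_i = 0$) are dropped with a warning; a *used* stratum with fewer than
two samples has an undefined SE and is an error by default
(`drop_short_rows = TRUE` drops such strata instead, making the estimates
conditional on the sampled strata — the pipeline uses this because small
synthetic scenes routinely map classes that the validation polygons
missed).

# Change accounting

Transition matrices cross-tabulate the two epochs over cells valid in
*both*; cloud/nodata cells in either epoch are excluded and the valid-cell
count is reported so percentages stay well-defined. Row sums equal epoch-1
class counts, column sums epoch-2 counts, and summing 15-class flows into
categories equals the category-level matrix (both properties are tested).

The annual rate is continuous-compounding,
$r = (100/t)\,\ln(A_1/A_2)$ %/yr, positive for loss. This is a deliberate
choice over the simple quotient: for the published forest areas (1,375 →
1,294 thousand ha over 27 years) the compound formula reproduces the
printed 0.225 %/yr while net-percent-divided-by-years gives 0.218 — the
arithmetic decided the formula. The quoted study-period "deforestation
rate of 2.7 %" has no stated definition and is not derivable from the
printed tables; `study_period_loss()` exposes a gross
forest-to-(agriculture ∪ other) fraction as an explicitly experimental
interpretation, and no acceptance target is attached to it.

# Fragmentation

`fad_map()` computes Forest Area Density — for every *forest* cell, the
fraction of forest cells in the centred $w\times w$ window — via an
integral image that is bit-equal to naive counting (tested on random
grids). Canonical scales are $w \in \{7, 13, 27, 81, 243\}$ cells
(4.41–5,314.41 ha at 30 m; where a summary table elsewhere prints 15.2 and
5,310.4 ha, the cell-count definition is taken as authoritative).

Numerical conventions that the interior magnitudes depend on:

* **Edge rule**: off-raster cells count as non-forest and the denominator
  stays $w^2$, so map edges are conservative (GUIDOS-like).
* **Nodata**: cloud cells count as non-forest in the numerator; cells
  whose window is more than half nodata are flagged `unreliable`.
* **Interior** is FAD ≥ 0.9, threshold inclusive.
* **Class bins** rare [0, 0.1), patchy [0.1, 0.4), transitional
  [0.4, 0.6), dominant [0.6, 0.9), interior [0.9, 1]: the published figure
  does not list its bin edges, so these are a package convention whose top
  bin is pinned to the interior rule.

# Transition-risk models

For each source category the outcome space is exactly three-valued: stay,
or convert to one of the two alternative vegetated categories; cells
moving into alpine or *other* fall outside the design and are excluded
with a reported count. The multinomial logit (baseline = stay) is fitted
by Newton–Raphson on the analytic score and Hessian with step halving and
a BFGS fallback; the intercept-only closed form
$\beta_{0k} = \ln(n_k/n_\mathrm{stay})$ anchors the independent oracle
tests.

Design choices where the study description is silent:

* **Standardization**: continuous covariates are z-scored once on the full
  observation set (subsample fits reuse the same scaling); needed for
  stable optimisation and unit-comparable RRRs. Signs are unaffected.
* **Subsampling**: fractions are drawn *without* replacement (a subsample,
  not a bootstrap), 10 % × 1,000 replicates in the reference design.
  Replicates whose subsample misses an outcome or fails to converge are
  excluded and counted.
* **Confidence intervals**: 2.5/97.5 percentiles of the replicate
  estimates (the reference method is unstated; percentiles are the natural
  summary of a replicate ensemble and make no normality assumption).
* **Categoricals** are one-hot coded against their first level.

`relative_risk_ratios()` is the exact exp-transform of the coefficient
table — no refitting — so CI ordering is preserved by monotonicity.

# The synthetic landscape: what it emulates, what it does not

The generator is the package's ground truth and its defaults are the
stated world of the motivating landscape:

* elevation 420–5,882 m as a smooth random field (FFT-smoothed Gaussian
  noise, autocorrelation length `noise_scale` = 8 cells), rescaled exactly
  to the range;
* epoch-1 classes by elevation band, snow near the summits, steep high
  terrain as rock (a slope-quantile rule, because compressing kilometres
  of relief into a small grid makes physical slope thresholds
  meaningless), rivers in the lowest 3 % of the relief, and a
  distance-decaying human-impact gradient (settlement → paddy/grassland →
  clearcut → secondary/shrub) around `n_villages` = 5 low-elevation
  villages with intensity 0.6;
* covariates derived from the terrain: lapse-rate temperature
  $T = 25 - 6.5\,z/1000$ °C *plus smooth microclimate noise (sd 2.5 °C)* —
  the noise is essential, a purely deterministic lapse is perfectly
  collinear with elevation and makes the transition model unidentifiable;
  precipitation 4,000–6,000 mm rising with elevation and along a west–east
  moisture gradient; Euclidean distances to villages, towns, a road
  transect that serves only about half the villages (again for
  identifiability against distance-to-village), and rivers;
* epoch-2 categories drawn per cell from the truth multinomial logit over
  standardized covariates. Truth intercepts encode the headline
  persistence probabilities at covariate means — 94 % (forest), 59 %
  (shrubland), 68 % (agriculture/developed) — and effect signs encode the
  published qualitative findings (steep/remote/cold persists; warm,
  village-near land converts). Because covariates vary, the *realized*
  mean stay fraction sits below the at-the-mean value (Jensen's
  inequality); the zero-slope configuration recovers the intercept
  probabilities exactly within binomial error, and that is what the
  generator test asserts;
* clouds as thresholded smoothed noise covering exactly
  `cloud_fraction` = 0.17 of epoch 2, as contiguous blobs so gap filling
  is exercised realistically;
* 70 training and 20 validation polygons per class (8–25 cells,
  connected, single-class, role-disjoint), with partial sets and a warning
  where a class is too rare — which on small test grids is the norm, so
  the test suite passes scaled-down counts explicitly;
* three synthetic spectral bands with fixed, well-separated class
  signatures (0.25 spacing, noise sd 0.05), standing in for reflectance.

Not emulated: radiometric structure of real imagery, fire dynamics,
mixed pixels, registration error, seasonal phenology. A green end-to-end
test therefore establishes that the *pipeline machinery* is correct and
deterministic — not that any particular real landscape would be mapped at
the measured accuracy.

# Determinism and degenerate inputs

Every stochastic operation takes or derives a seed; the pipeline derives
per-stage seeds from one master seed and writes a manifest of seeds,
runtimes and output hashes, and two runs with the same config are
bit-identical (tested). Degenerate inputs fail loudly: codes outside the
scheme, misaligned grids (first mismatch named), even or oversized FAD
windows, empty feature masks, single-class training sets, zero-village
configs with nonzero degradation, strata with undefined SEs.

# Known limitations

* The ASCII-grid interface carries no CRS; co-registration is asserted,
  not reprojected.
* The random forest restricts candidate-feature resampling to each split
  as designed, but grows unpruned trees to a depth cap of 30; with many
  thousands of polygons per class, training cost grows linearly in trees ×
  samples × depth.
* Percentile CIs from 10 % subsamples are wider than full-data asymptotic
  CIs by roughly $\sqrt{10}$; they are a robustness device, not an
  efficiency claim.
* `study_period_loss()` is an interpretation of an under-specified
  published quantity and should not be compared against it.
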