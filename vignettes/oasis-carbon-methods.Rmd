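---
title: "Methods: carbon accounting and driver detection in an arid oasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carbon accounting and driver detection in an arid oasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oasiscarbon)
```

## The problem and the model chain

An oasis ecosystem's carbon stock is the sum, over land-use classes, of a
per-class carbon density times the class area (the InVEST carbon-module
accounting scheme):

$$D_i = D_{i,a} + D_{i,b} + D_{i,s} + D_{i,d}, \qquad
  S_{total} = \sum_{i=1}^{n} D_i \, A_i,$$

with aboveground, underground (root), soil and dead-organic pools. The
densities themselves are not observed wall to wall: they are inverted from
sparse field samples through machine-learning regression on a raster
predictor stack, assembled into pools with literature conversion constants,
and projected to unobserved epochs through regional climate ratios. Spatial
heterogeneity of the resulting stock is then attributed to environmental
and human drivers with the geographical-detector statistic. This vignette
records the modelling decisions, parameter meanings, numerical conventions
and limitations of each stage.

## Sample handling and variable selection

**SPXY splitting.** Calibration/validation partitioning uses the joint
X–y distance: predictors are min–max scaled, the Euclidean predictor
distance and the absolute response difference are each normalised by their
maximum over all pairs and summed, the two mutually most distant samples
seed the calibration set, and samples are added greedily by the max–min
rule until `round(n · fraction)` are selected. With the default fraction
0.7 this yields 113/49 for n = 162 and 67/29 for n = 96 — the partition
sizes of the emulated field campaigns. The rule is deterministic, and
permutation-equivariant up to exact distance ties (measure zero for
continuous data).

**Pearson screening.** A predictor is retained when its correlation with
the response is significant under the two-sided t test at `alpha = 0.05`.
The level is a package default, configurable, and can be replaced by an
absolute-|r| cutoff; significance screening adapts to sample size, which a
fixed |r| cutoff does not. Zero-variance predictors are dropped with a
warning rather than an error, since a constant layer is a data accident,
not a caller mistake.

**CARS.** Fifty Monte-Carlo runs; each run fits SIMPLS partial least
squares (autoscaled predictors, centred response, component count capped at
10) on a random 80 % of samples, ranks variables by absolute standardized
coefficient, and retains a number that follows the exponential decay from
all p variables at the first run to two at the last. Retention combines
forced removal of the clearly weak with weight-proportional sampling (the
adaptive reweighting), so the retained-set size follows the schedule
exactly while weak variables still compete stochastically. Each run's set
is scored by 5-fold cross-validated RMSE on the full calibration set; the
minimiser wins. Predictors are standardized before PLS throughout — the
selectors' behaviour should not depend on predictor units.

**IRIV.** Each round draws a 500-row binary inclusion matrix (each model a
random half of the current variables), computes every row's minimum
cross-validated RMSE over the PLS component path, and classifies each
variable by the paired difference between models without and with it:
positive mean difference and p < 0.05 (paired t) is strongly informative,
positive but non-significant weakly informative, non-positive and
non-significant uninformative, non-positive and significant interfering.
Uninformative and interfering variables leave; rounds repeat until none
do; a backward elimination on cross-validated RMSE finishes. The
inner loop (tens of thousands of small PLS fits) is compiled C++; PLS with
the full component count is verified in the tests against ordinary least
squares, its closed-form limit.

## Regression and evaluation

RFR uses 500 bootstrap-aggregated trees with ⌊√p⌋ candidate variables per
split; SVMR uses a radial-basis kernel with cost and gamma chosen by a
seeded 5-fold grid search (cost 2⁰…2⁶, gamma (1/p)·2⁻²…2²). These are
conventional defaults, all overridable; the comparison harness treats
hyperparameters as part of the method. Accuracy uses R², RMSE, the n−1
standard deviation and RPD = SD/RMSE, banded at 1.4 and 2. Model selection
is by validation R² with lower RMSE as tie-break. Raster inversion clips
predictions below zero (counted and reported) because a biomass or carbon
density is physically non-negative; tree ensembles cannot extrapolate
below the training range, so clipping is rare and small.

Whether evaluation happens on raw or transformed responses is a modelling
choice; metrics here are computed on the raw response scale.

## Pool assembly and climate correction

The assembly constants — the 0.45 biomass-to-carbon conversion, per-class
root-to-shoot ratios (0.10, 0.30, 3.70, 4.50), field bulk densities (1.53,
1.48, 1.71, 1.24 g·cm⁻³), the 0–20 cm depth, the one-tenth dead-organic
fraction and the 41.4 % construction-land green coverage — are standard
values for arid-region accounting and live in one validated
`pool_parameters()` object. Conventions worth stating:

* Water cells carry zero in all four pools (aquatic carbon out of scope).
* Construction cells take green-coverage-scaled copies of *all four*
  forest-grassland pool means, from the same scene and epoch (the source
  being corrected), not from a fixed reference year.
* The soil formula's kg·m⁻² output is converted to g·m⁻² at the assembly
  boundary; every density in the package is g·m⁻², every stock in tonnes,
  every area in km² (1 g·m⁻² over 1 km² is exactly 1 t, which makes the
  unit tests sharp).

Climate correction multiplies the reference-epoch class table by ratios of
literature regressions: soil by (3.3968 P′ + 3996.1)/(3.3968 P″ + 3996.1),
biomass by e^{0.0054 (P′−P″)} · (28 T′ + 398)/(28 T″ + 398), with primes
for the target epoch and double primes for the reference. Only ratios are
used, so the absolute units of the regression constants cancel — the
correction is dimensionless by construction. The dead pool, being defined
as a fraction of aboveground biomass, scales with the biomass coefficient.
Temperature does not correct the soil pool (its dependence is much weaker
and no usable regression exists). Correction operates on class-level
tables, not per-cell rasters, because the parameters being projected are
class parameters; the reference epoch (2019 by default) is configurable.
Scenario epochs take their climate from the matched SSP pathway: EPS→
SSP126, NDS→SSP245, CDS→SSP370, EDS→SSP585.

## Stock accounting, change and transitions

Per-epoch totals use class-table lookup as the canonical mode (the
reference year additionally has true per-cell pool rasters). Change
classification is relative to the earlier epoch's cell value at ±5 %;
cells starting at zero are "unchanged" only if they stay at zero. The
transition decomposition assigns each converting cell the density
difference between its destination class (later table) and origin class
(earlier table), and each stable cell its class's table change; summed,
these reproduce the inter-epoch total difference exactly — an identity the
acceptance suite checks to 10⁻⁶ t on the full 200 × 200 grid. Epoch pairs
default to consecutive years plus last-year→scenario, but any pair is
accepted.

## Driver detection (OPGD)

The q statistic uses population (divisor-N) variances, the geodetector
convention: q = 1 − SSW/SST. Candidate discretizations are the five
standard methods with k ∈ {3,…,8}; the (method, k) pair maximising q wins,
with ties to smaller k, then method order. Natural breaks use an exact
O(k·n²) Fisher–Jenks dynamic program; inputs longer than 1024 values are
first thinned to 1024 quantile-spaced points, which changes breaks
negligibly while keeping the program exact on its input. Significance uses
label permutation (999 by default, seeded) — assumption-free, unlike the
noncentral-F formulation, and directly testable against a uniform null.
The response is sampled at every cell by default (desk-scale grids);
a stride flag exists for larger rasters.

Interaction detection reuses each factor's optimal single-factor
discretization and computes q on the cross-product strata. Because the
cross-product refines both marginal stratifications, q₁₂ ≥ max(q₁, q₂)
always holds here; the boundary case q₁₂ = max (within ε = 10⁻⁹) is
assigned to the lower category (univariate weakening), so only genuinely
larger joint power counts as enhancement. Influence bands follow the
standard cutpoints: q ≥ 0.3 main, ≥ 0.2 strong, ≥ 0.1 medium, else weak.

## The synthetic scene: what it emulates, and what it does not

The generator produces the statistical structure the pipeline assumes,
with everything derived from one seed:

* **Geometry.** 200 × 200 cells at 10 m (all stages are resolution-agnostic;
  this size keeps full runs under a minute on one CPU — the acceptance
  suite and script use it).
* **Gradient.** An elliptical oasis core whose suitability decays into
  desert, plus a smoothed Gaussian random field; class assignment walks the
  suitability ranking (garden and arable innermost, unused outermost), so
  areal fractions hit their targets exactly up to integer rounding.
* **Epochs and scenarios.** Later years drift the class-area targets
  (arable and garden grow at the fringe, unused shrinks) and jitter the
  suitability surface, so transitions concentrate at class boundaries —
  the same effect as morphological fringe growth, with exact area control.
  Scenario drifts differ in sign: forest-grassland grows under EPS,
  construction under EDS, arable under CDS. The drift rates are
  configuration, not claims about any real landscape.
* **Fields.** AGB is lognormal around per-class means (garden 1100 >
  arable 750 > forest-grassland 450 > unused 120 g·m⁻²), clipped to
  [5.83, 3416.5] — strongly right-skewed, median well below mean, matching
  the prevalence of low values in arid-region biomass campaigns. SOC is a
  correlated truncated normal per class within [0.67, 10.20] g·kg⁻¹; its
  class means (7.0, 5.0, 4.0, 2.3 g·kg⁻¹) were chosen so the pool
  arithmetic reproduces the reported ranking and approximate magnitudes of
  class total densities in arid oasis studies (garden ≈ 2.7, forest ≈ 2.4,
  arable ≈ 1.9, unused ≈ 0.9 kg·m⁻²).
* **Predictors.** 44 named layers: five noisy transforms of latent AGB,
  five of latent SOC (a real inversion stack carries soil-relevant
  covariates too), a correlated-nuisance block, and pure noise. Observation
  noise on field samples is multiplicative Gaussian at 10 % CV.
* **Drivers.** Vegetation cover is built as a tight monotone function of
  latent carbon — the planted dominant factor the detection stage must
  recover; the other eight mix the oasis gradient with independent smooth
  fields at lower coupling; soil type is categorical.

What passing tests on this scene do **not** show: robustness to sensor
physics, georeferencing error, cloud or phenology artefacts, spatially
structured sampling bias, or class-dependent observation noise — none of
which the generator emulates. Real per-class areal fractions of any
particular oasis are likewise not claimed; the defaults are plausible
round numbers.

## Numerical conventions and degenerate inputs

* All randomness flows from named seeds; identical configuration and seed
  reproduce every run-manifest checksum bit for bit.
* Rasters are matrices with `NA` nodata, written as Esri ASCII grids
  (12 significant digits, integer codes for categorical maps); tables are
  CSV. Both round-trip losslessly at that precision.
* Degenerate inputs fail early with named causes: identical samples in
  SPXY, zero overall variance in q, unknown land-use codes, missing table
  rows, grid mismatches, infeasible discretizations (too few distinct
  values), zero-area classes configured with nonzero means.
* Boundary conventions: RPD bands close at the left (RPD = 2 is
  "strong"); q influence bands close at the left; interaction boundary
  ties go to the weaker category; SPXY tie-breaks take the lowest index.

## Known limitations

Soil carbon below 20 cm, aquatic carbon, monetary valuation and
sequestration-over-time accounting are out of scope. The climate
correction applies region-mean temperature and precipitation per epoch —
within-region climate gradients do not move class parameters. The
literature regressions behind the correction are used as given, not
refitted. CARS and IRIV assume an approximately linear
predictor–response backbone for their PLS scoring; strongly non-monotone
signals favour the screening-only variable sets, which the comparison
harness will then select on its own.
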