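---
title: "Methods: a hierarchical climate-vegetation-habitat cascade for alpine species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hierarchical climate-vegetation-habitat cascade for alpine species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`alpcascade` implements a three-level species-distribution cascade for
alpine ecosystems, of the kind used to project climate-change impacts on
alpine specialists such as the Rock Ptarmigan. The levels reflect a
hierarchy of controls:

1. **Climate → alpine vegetation zone** (sub-model B1). At the scale of a
   1-km climate lattice, macroclimate decides whether the alpine vegetation
   zone can occur at all. Occurrence is modelled by an additive logistic
   model (`mgcv::gam`, binomial, logit link) with a bivariate thin-plate
   smooth of warmth index (WI) and coldest-month minimum temperature (TMC),
   and univariate smooths of summer precipitation (PRS) and maximum
   snow-water equivalent (MSW). Smoothness is selected by REML.
2. **Topography → community area fractions** (sub-model B2). Within the
   zone, micro-topography decides how much of each 100-m cell the three
   alpine communities cover (*Pinus pumila* scrub, snowbed grassland,
   fellfield). One random-forest regression per community maps five terrain
   predictors (slope, aspect, curvature, TWI, ridge distance) plus the B1
   zone probability to the community area fraction. Variable importance is
   increased MSE under seeded column permutation.
3. **Vegetation → territories** (sub-model A). On a 300-m territory
   lattice, presence/absence of territories is modelled by an additive
   logistic model with a bivariate smooth of (ridge distance, *P. pumila*
   fraction), univariate smooths of the fellfield and snowbed fractions,
   and `log(number of surveys)` as an offset so unequal survey effort is
   absorbed on the linear predictor rather than confounded with habitat
   quality. Term importance (IOV) is the summed Akaike weight over all
   2^3 subset models, the combined (DR, AF_Pp) smooth entering as a single
   unit.

Future habitat is projected by delta-method downscaling of GCM anomalies
onto the baseline climatology, recomputing the bioclimatic indices, and
pushing the result down the fitted cascade with topography held constant
and all thresholds frozen at their training values. Ensembles are
summarised by the cell-wise median probability, binary habitat at the
frozen threshold, and per-cell counts of scenarios under which currently
suitable habitat is sustained.

# Bioclimatic indices

Per climate cell and month set \(T_m\) (monthly mean temperature, deg C),
\(N_m\) (monthly mean daily minimum) and \(P_m\) (monthly precipitation, mm):

* **WI** \(= \sum_m \max(0, T_m - 5)\) (deg C month) — a heat sum of growing
  conditions.
* **TMC** \(= \min_m N_m\) — extreme cold.
* **PRS** \(= \sum_{m=5}^{9} P_m\) — growing-season water supply; "summer"
  is read literally as calendar months May-September.
* **MSW** — the annual maximum of a daily degree-day snowpack balance:
  precipitation on days below the rain/snow threshold accrues as snow;
  potential melt is `degreeDayFactor * max(0, T - meltBase)`, capped at the
  pack; MSW is the series maximum. Mass balance (total snowfall - total
  melt = final pack) holds exactly by construction and is asserted in the
  tests.

**Snow parameters.** The degree-day constants are not observable from the
package's inputs, so mid-range values from standard degree-day hydrology
are used and exposed in `snowModelParams()`: rain/snow threshold 2 deg C,
melt factor 4 mm per deg C per day, melt base 0 deg C.

**Daily forcing.** The snow model needs daily weather while the
climatology is monthly. Daily temperature is a periodic cubic-spline
interpolation of the twelve monthly means through month midpoints (a
smooth seasonal curve honouring every monthly value, which a single
sinusoid cannot) plus seeded day-to-day Gaussian noise (s.d. 2 deg C)
shared across cells — one mountain region shares its weather. Wet days are
drawn per day at a fixed frequency (0.4) and each month's precipitation
total is split equally over its wet days, so monthly totals are preserved
exactly. The hydrological year runs 1 September - 31 August so one winter
pack is contiguous. Because the noise and wet-day pattern depend only on
the synthesis seed, an identity scenario reproduces baseline indices bit
for bit, and a uniform warming delta changes WI, TMC monotonically upward
and MSW monotonically downward.

# Downscaling

GCM anomalies are coarse fields of additive temperature differences
(applied to monthly means and minimums separately) and multiplicative
precipitation ratios. They are interpolated bilinearly to the climate
lattice, treating coarse values as cell-centre points and holding values
constant beyond the outermost centres; "simple linear interpolation" is
thus read as bilinear, the simplest consistent two-dimensional choice. No
bias correction between the observational climatology and the GCM baseline
period is applied.

# Terrain derivatives

Algorithms are fixed, standard and testable: Horn 3x3 slope/aspect
(aspect = downslope compass direction, NA on flat cells),
Zevenbergen-Thorne curvature (convex-up positive), D8 single-direction
flow accumulation after a minimal iterative pit fill, TWI
\(= \ln(a/\tan\beta)\) with specific catchment area \(a\) =
accumulation x cell size and a slope floor of \(\tan\beta \ge 10^{-3}\),
and ridge cells defined as cells whose flow accumulation on the *inverted*
DEM exceeds a configurable quantile (default 0.99) — water poured on the
upside-down landscape collects along the divides. Ridge distance is the
exact Euclidean distance to the nearest ridge cell. Derivative stencils
use edge replication so every cell has a value, but the one-cell border is
excluded from model-fitting tables. Aspect enters the forests as raw
degrees (one predictor, matching the single "slope direction" variable);
a sine/cosine encoding was considered and rejected to keep the predictor
count faithful.

# The synthetic study system

The package ships no field data; the generator builds a self-consistent
study system with known truth so that every fitting stage has a
recoverable answer.

* **Geometry.** Default domain 12 km x 18 km, tiled exactly by the 100-m
  terrain lattice (21,600 cells), the 1-km climate lattice (216 cells) and
  the 300-m territory lattice (2,400 cells). The sizes keep a full
  generate-fit-project cycle around a minute on one CPU while leaving
  2,400 territory cells for the occupancy model, comparable to the
  recovery-experiment sizes the tests use.
* **DEM.** A north-south ridge spine (crest undulating just below the
  3,000-m peak) with Gaussian flanks plus a smoothed seeded random field;
  `ruggedness` scales the whole relief, so 0 gives flat ground and the
  spine guarantees the ridge extractor a known answer.
* **Climate.** Monthly means follow a maritime temperate sea-level cycle
  minus a 6 deg C/km lapse; minimums sit 6 deg C below means (never above);
  precipitation has a mild orographic factor. Gaussian noise: 0.3 deg C on
  temperatures, 10% relative on precipitation.
* **Zone truth.** Logistic in the bioclim indices with a dominant negative
  WI effect and a smaller positive MSW effect
  (intercept 4.5, WI -0.45, MSW +0.001), calibrated so the alpine zone
  occupies the upper elevations under the baseline climate and collapses
  under ensemble-scale warming — the qualitative behaviour of the emulated
  system. Warmth excludes the zone; snow sustains it.
* **Vegetation truth.** Community fractions are zone suitability times a
  terrain response: *P. pumila* decays exponentially with ridge distance
  (scale 250 m), snowbed increases with TWI, fellfield with convexity;
  maxima 0.50/0.28/0.20 keep sums below 1. Fractions below a 0.005
  minimum-mapping-unit floor are mapped as absent, and Gaussian noise
  (s.d. 0.03) is applied only where a community truly occurs — a digitised
  vegetation map contains exact zeros, and the any-cover zone-labelling
  rule depends on them.
* **Territories.** Per-survey occupancy is logistic in the aggregated
  fractions and ridge distance (intercept -6, AF_Pp +16, AF_Sg and
  AF_Ff +5, DR -0.0015/m: ~4% prevalence, occupancy concentrated in
  near-ridge high-*P. pumila* cells). Observed presence is Bernoulli with
  detection probability \(1-(1-p)^{n}\) over \(n\) surveys (1-5 per cell),
  the complementary form that makes a fit-time effort offset identifiable;
  unsurveyed cells are excluded.

**What the generator does not emulate:** spatial autocorrelation of
residuals beyond the smooth responses, detection covariates other than
effort, interannual climate variability, disturbance, and soil. Passing
recovery tests therefore demonstrates that the machinery recovers planted
structure under the stated noise — not that the models are adequate for
any particular real mountain range.

# Numerical and design choices

* **Zone labels** (construction unstated for the emulated study): a
  climate cell is "zone present" when the mean total community cover of
  its fine cells exceeds 0 (any cover). The threshold is exposed.
* **B1 fitting resolution**: at climate resolution (one row per climate
  cell) rather than on replicated 100-m cells; replication would only
  re-weight the likelihood. Zone probabilities are resampled to 100 m by
  nearest neighbour, preserving the coarse values exactly.
* **Forests**: 500 trees, `mtry = floor(p/3)` = 2, seeded; training tables
  above `maxRows` (pipeline default 5,000) are subsampled with a seed.
* **Thresholding**: the habitat threshold is the largest value keeping
  training sensitivity at or above 0.95 (ties resolved upward, the most
  conservative qualifying extent). Training metrics and the threshold for
  the territory model are computed on predictions standardised at one
  survey, so the threshold applies directly to projection maps, which are
  also standardised at one survey.
* **Bootstrap validation** resamples scored training rows with replacement
  (100 reps) against the once-fitted model; the optimism of validating on
  bootstrap replicates of the training data is accepted and documented.
* **AIC** for the additive models uses mgcv's effective degrees of freedom.
* **Fraction sums** above 1 after prediction are rescaled proportionally,
  never by truncating one community first (order independence).
* **Even-count ensemble medians** average the two central order statistics.
* **"Sustained" habitat** = habitat under the current model AND under a
  scenario's projection; agreement counts are reported over currently
  suitable cells (0 elsewhere). Both the median-based binary map and the
  agreement count are exposed, since either can define "remaining" cells.
* **Degenerate inputs**: single-class training data, zero-survey rows,
  non-nesting grids, scenarios not covering the domain, and landscapes
  with no ridge cells all raise typed errors rather than fitting silently.

# Limitations

Saturation behaviour at extreme warming depends on extrapolation of the
territory model's bivariate smooth into the unobserved corner (ridge
distance small, *P. pumila* fraction near zero); with the default truth a
+10 deg C scenario leaves zero to a handful of borderline cells depending
on the landscape seed. D8 routing is single-direction; no
multiple-flow-direction option is provided. The survey offset is the
standard `log(n)` logit construction, a first-order approximation to the
complementary detection process used by the generator. No spatial
autocorrelation terms are fitted, mirroring the emulated design.

# Problem sizes

The shipped tests and the acceptance script use the default 12 x 18 km
system (21,600 fine cells), 24-member synthetic GCM ensembles,
2,000-5,000-row recovery experiments, 100 bootstrap repetitions and
500-tree forests on 5,000-row subsamples — sizes chosen so a complete
cycle runs in about a minute and the whole suite in a few minutes on one
CPU.
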