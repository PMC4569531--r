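---
title: "Methods: baseline analysis of a tall eucalypt plot network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: baseline analysis of a tall eucalypt plot network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tallstand)
```

`tallstand` implements the baseline analyses of a network of 1-ha
permanent forest plots in tall eucalypt forest: census management,
community importance statistics, allometric carbon accounting, stand
structure, canopy cover and carbon–climate model selection. This
vignette is the package's own account of those methods — the models and
their assumptions, the defaults and why they were chosen, the numerical
conventions, and what the synthetic data generator does and does not
emulate.

## The census data model

A census is three tables. The **stem table** has one row per tagged stem
with DBH ≥ 10 cm: species, diameter (cm) at the point of measurement
(1.3 m by default; higher above buttresses or deformities), plot
coordinates x, y ∈ [0, 100] m from the georeferenced corner, canopy
position (suppressed / dominant / co-dominant / emergent), growth stage
(regrowth / regenerating / mature / senescent), a stem-form code, live
status with a mortality-mechanism code for dead stems, an optional
measured height, and a buttress flag. Every stem of a multi-stemmed tree
is its own record; no tree-level deduplication is attempted, so stocking
density deliberately overestimates individual trees. The **plot table**
carries region, area, climate (MAT °C, MAP mm/yr, pan evaporation
mm/yr), elevation and the `agc_excluded` flag. The **species table**
maps each species to a community guild — eucalypt (`Euc`, including
*Corymbia*), wet sclerophyll (`Scl`) or rainforest (`RF`).

Protocol conformance is checked by `validate_census()`, which returns
violations as ordered data rather than raising errors: field data are
routinely imperfect and the analyst needs the full list, not the first
failure. Mortality and stem-form code vocabularies are deliberately
unconstrained (any string is accepted) because protocol code lists vary
between networks and manual revisions; the one structural rule enforced
is that a mortality code implies a dead stem.

Dead stems stay in the census but are excluded from all live-stand
metrics (basal area, stocking, importance values, carbon) unless
`include_dead = TRUE`; the baseline tables describe the live stand.

## Importance values

`importance_values()` ranks taxa by the sum of three percentage shares:
relative density (stem share), relative dominance (basal-area share) and
relative frequency. Frequency is **normalized across taxa**
(`100·f_i/Σf`, where `f_i` counts occupied plots) rather than the raw
percentage of plots occupied. The raw occupancy percentage cannot be a
component of a 0–300 importance value — it does not sum to 100 across
taxa — so it is exposed as a separate `occupancy_pct` column instead.
Regional tables are computed by pooling stems across the region's plots;
a `method = "plot_mean"` alternative averages per-plot shares, since
both conventions exist in practice. Both preserve the column-sum
invariants (each component sums to 100, IV to 300), which the test suite
asserts over randomized censuses.

## Allometric carbon

Tree biomass uses the standard generic ln–ln diameter allometry
`AGB = cf·exp(α + β·ln DBH)` with an optional multiplicative
back-transform correction `cf`, one equation per guild scope: eucalypts
(with *Corymbia*) and everything else. Coefficients are configuration,
not constants: the generic published calibrations are not reproduced
here, so the package ships only a synthetic, clearly-labelled
coefficient file (`inst/extdata/allometry_synthetic.json`) and all tests
run on synthetic coefficients. Plot AGB sums live-stem biomass to t/ha
and AGC applies a carbon fraction of 0.50 (configurable).

Buttressed stems are handled by measurement convention (diameter
recorded above the buttress, at a recorded point of measurement); where
that is insufficient — entire plots dominated by heavily buttressed
trees — the plot-level `agc_excluded` flag removes the plot from all
network carbon statistics while leaving it in every non-carbon analysis.

`agc_by_diameter_class()` partitions carbon over lower-closed diameter
classes (default 10–50, 50–100, 100–150, > 150 cm), defaulting to the
eucalypt component because the overstorey carbon distribution is the
quantity of interest; shares always sum to 100 %.

## Stand structure

Basal area is `Σ π(DBH/200)²` per hectare and is additive over any
partition of the stems. Diameter distributions use lower-closed,
upper-open bins starting at the 10-cm admission threshold
(`[10,20), [20,30), …`) so each stem belongs to exactly one bin; the
binning convention is a package decision, documented rather than
inherited. The diameter–height curve `height = a + b·ln(DBH)` is fitted
by OLS; the natural logarithm is used (the choice only rescales `b`).
Height summaries use measured heights only — heights are recorded for a
subset of stems, and imputing the rest from the fitted curve would
manufacture precision; predictions are available explicitly via
`predict()`. Regional dominant-height summaries are reported under both
existing conventions (mean of per-plot means, and pooled over stems)
because the two differ and neither is canonical.

## Canopy cover

A hemispherical photograph is reduced to one grayscale channel scaled to
[0, 255] and thresholded: pixels strictly below 125 are canopy, pixels
at or above it are sky (the boundary convention and the threshold are
both configurable). For colour images the blue channel is the default
reduction — sky/foliage contrast is strongest in blue, the standard
practice in hemispherical photography — with red, green and a Rec. 709
luminance alternative. No circular fisheye mask is applied by default
since frame geometry varies between cameras; `mask_radius` enables one.
Plot cover is the unweighted mean over the 16 fixed photo stations.

## Carbon–climate model selection

`fit_agc_climate()` regresses plot AGC on candidate predictor sets drawn
from MAT, MAP and P:E (= MAP / pan evaporation, a water-availability
index), always including an intercept, and ranks candidates by AIC under
the full Gaussian log-likelihood: `AIC = n(ln 2π + ln(RSS/n) + 1) + 2k`
with `k = predictors + intercept + variance`. This matches the
convention of mainstream statistical environments so ΔAIC values are
portable. Candidates within ΔAIC < 2 of the best are flagged
`equivalent_support`; exact ties rank the simpler model first. Two
numerical edge cases are handled explicitly: rank-deficient designs are
rejected naming the collinear predictors, and a numerically perfect fit
(RSS at machine-noise level, where the Gaussian likelihood degenerates)
is reported as `aic = -Inf` with the parameter count breaking ties — so
an exactly constant response selects the null model, as the parsimony
penalty intends.

The climate envelope of a reference estate is the convex hull of its
(MAT, MAP) cloud after standardizing each axis by the reference standard
deviation — the least-assumption definition of an envelope drawn around
a point cloud. Boundary points count as inside. The reported distance is
0 for inside points, otherwise the standardized Euclidean distance to
the nearest hull edge; this makes "a query equal to a reference point
has distance 0" hold for interior reference points too. Height-class
labels (`25–35 m`, `35–45 m`, `> 45 m`, lower-closed) are assigned from
*predicted* heights supplied by the user: the height–climate model that
produces them is external input, not hard-coded, because its form and
coefficients belong to the dataset that trained it.

## The synthetic census generator

`generate_network()` draws a full network whose defaults are the study
conditions the analyses assume: 48 one-ha plots in 7 regions spanning
MAT 6.6–20.5 °C and MAP 853–1895 mm, censused 2012–2015. Each plot
receives:

* a **dominant eucalypt overstorey** with lognormal DBH (median 70 cm,
  sdlog 0.37). This calibration puts the 10-cm-binned cohort mode inside
  [50, 100) cm for ≳ 95 % of plots while leaving ≈ 2 % of eucalypts
  above 150 cm, so the big-tree tail carries a realistic minority share
  of carbon (roughly 4/49/34/13 % across the 10–50/50–100/100–150/>150
  cm classes);
* a **non-eucalypt understorey** that is exponential-like above the
  10-cm threshold in regions with prolific recent recruitment
  ("skewed") or lognormal-peaked where recruitment was pulsed
  ("peaked"), with a region-specific rainforest fraction (zero in the
  west, where no rainforest flora occurs);
* **measured heights** for a 15-stem subset per stratum from
  `height = a + b·ln(DBH) + ε` (overstorey a = 7.5, b = 10, sd = 3 m,
  giving ≈ 50 m dominants at 70 cm; understorey a = 2, b = 8,
  sd = 2.5 m);
* a **3 % dead cohort** with protocol-style mortality codes, added on
  top of the live stand.

Carbon is coupled to temperature by construction, not post-hoc editing:
each plot gets a target AGC of 400 tC/ha at 6 °C declining by
14.3 tC/ha per °C (so ≈ 200 tC/ha at 20 °C) plus N(0, 60²) noise, and
the overstorey and understorey stem counts are sized so the expected
allometric carbon of the drawn cohorts (90 % eucalypt share) meets the
target. Stem counts respond to climate the way stand density would,
and the carbon accounting stays internally consistent — recomputing AGC
from the generated stems recovers the imposed slope within sampling
error, which the test suite checks over 100 replicate networks.

Pan evaporation is not part of the emulated climate summary, so regional
ranges were chosen once on realism grounds: roughly 900 mm/yr in cool
highland Tasmania rising to 1800 mm/yr in the tropics, which puts the
P:E index in the observed 0.5–1.6 band. All draws derive from a single
master seed and the caller's RNG state is restored afterwards; the same
configuration is bit-reproducible.

**What the generator does not emulate** — and hence what passing tests
do not show about field data: spatial structure within plots
(coordinates are uniform; no competition, clustering or gap dynamics),
species–climate sorting beyond the regional pools, measurement error in
DBH or species identification, buttressed stems and the excluded-plot
scenario (exercised by hand-built fixtures instead), multi-census
dynamics, and any real allometric calibration. Recovery of the
carbon–temperature slope from synthetic data demonstrates the pipeline's
correctness, not the field result; the empirical slope, r² and AIC
values of a real network depend on the real plot data.

## Problem sizes and tolerances

The test suite runs randomized-property checks at 100 seeds for the
normalization and binning invariants, 100 replicate networks for
carbon-slope recovery, and 200 replicates of a 46-plot simulation for
the AIC power check — sizes chosen so the whole suite completes in a few
minutes while leaving the statistical assertions comfortable margins.
Exact algebraic identities (AIC formula, scalar-loop carbon oracles,
normal-equations OLS) are asserted to 1e-8 or tighter; stochastic
recoveries use explicit standard-error-based bands. Seeds are fixed
throughout.

## Known limitations

* Importance values treat each stem as an individual; multi-stemmed
  trees therefore inflate relative density slightly, consistent with the
  stocking convention.
* The climate envelope is a convex hull: it cannot represent concave
  climate spaces and is sensitive to outlying reference points.
* Canopy thresholding at a fixed cut-off has no exposure correction; the
  125 default assumes comparable exposure across photographs.
* The allometric form is diameter-only; height-and-diameter bivariate
  allometries are out of scope.
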