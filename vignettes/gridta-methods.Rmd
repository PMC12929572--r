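---
title: "Modelling daily air temperature on a fine grid: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling daily air temperature on a fine grid: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`gridta` estimates daily mean ambient air temperature (*Ta*, °C) on a
regular 500 m grid from a sparse station network and gridded predictors.
This vignette explains the statistical machinery, the choices behind it,
and what the synthetic-world tests do and do not demonstrate about real
data.

## The model and its assumptions

The estimator is a bagged regression-tree ensemble (random forest, via
`ranger`): trees grown on bootstrap samples with squared-error splitting,
predictions averaged arithmetically across trees. The forest makes no
distributional or stationarity assumptions, handles correlated predictors,
and captures non-linear predictor–response relationships — the reason it is
preferred here over kriging-style interpolators for data-sparse, physically
heterogeneous urban domains. Its known weakness is extrapolation: predictions
cannot exceed the range of training targets, so extremes beyond the observed
record are compressed. An ordinary least-squares baseline (`train_mlr`) is
fit on the identical features for comparison; the cellwise difference of the
two prediction surfaces (`delta_temp`) localizes where non-linearity
matters.

Model skill is always judged **at unsampled locations**: cross-validation
folds are groups of whole stations (`make_station_folds`), so the test
stations of a fold never contribute training rows. Reported CV metrics are
computed on the pooled out-of-fold predictions rather than averaged per
fold; for RMSE the two views are algebraically linked (the pooled square is
the size-weighted mean of fold squares; a unit test asserts this identity),
and pooling matches how observed-vs-predicted scatter is usually read.

R² is reported as the squared Pearson correlation of observed and
predicted values — the convention of a scatter-plot regression — with the
`1 − SSE/SST` form available as `r_squared_ss`. The two differ under
systematic bias; the correlation form is the reported default, and both are
exposed so the distinction is never hidden.

## Feature selection and tuning

Forward feature selection starts from the best single feature and greedily
adds whichever candidate most reduces the station-grouped CV RMSE, stopping
when the best addition improves by no more than `tol` (default 0: any
strict improvement continues). The selected set is the trajectory prefix
with minimal RMSE. A pair-start variant (`start = "pair"`) is available;
the single-feature start is the default because it matches the sequential
selector convention most users know. Selection runs jointly with a grid
search over `n_estimators` ∈ {300, 500, 700, 1000}, `max_features` ∈
{auto, sqrt} and `max_depth` ∈ {10, 15, 20} — 24 combinations — with exact
ties broken toward fewer features, then fewer and shallower trees.
`max_features = "auto"` means all *p* features at every split (the
regression convention); `"sqrt"` means ⌈√p⌉. To cut search cost the
selection table can be a 50 % sample stratified by equal-width temperature
bins (`stratified_sample`, 10 bins by default; the per-bin floor plus
largest-bin remainders make the global count exact).

The hold-out for external validation is 10 % of stations
(half-away-from-zero rounding, so 48 stations give 5), chosen as the
*first* random subset whose observed temperatures differ from the remainder
by a two-sided Welch t-test at p < 0.05. Selecting a
*different*-distribution hold-out is deliberately stricter than a random
one: it probes generalization to places unlike the training network. Welch
and two-sided are the package's choices where the test variant is
otherwise unspecified, since station series lengths differ.

## Validation decomposition

`decompose_error` separates spatial from temporal skill. For every
station-year with at least `min_days` available days (default 300, so
incomplete years do not contribute noisy means), observed and predicted
annual means are computed. The *spatial* regression fits observed
station-year means on predicted ones; the *temporal* regression fits
observed daily anomalies (around the station-year mean) on predicted
anomalies, pooled per year and overall. Observed is always the response,
predicted the regressor. By construction the temporal component is
invariant to adding any per-station-year constant to predictions, and the
spatial component to adding any zero-mean within-station-year fluctuation —
both invariances are asserted in tests with closed-form constructions.

Permutation importance follows the mean-decrease-accuracy recipe on the
external hold-out: score the fitted model (R² by default; RMSE by flag,
sign-flipped so bigger still means more important), shuffle one feature
within the hold-out, re-score, and average the drop over ten shuffles.

## The synthetic world

`generate_world` builds a study-like testbed with fully known truth:

* **t2m** — a seasonal sinusoid (mean 20.3 °C, amplitude 3.5 °C, austral
  summer peak in early February), a 1.5 °C north–south gradient, a +1 °C
  urban-heat bump on a disc covering ~25 % of cells, a shared AR(1)
  day-to-day anomaly (sd 2 °C, φ 0.8) and small cell noise;
* **d2m** = t2m minus a strictly positive, seasonally varying dew-point
  depression, so relative humidity (Magnus form) never needs clipping;
* **lst** — t2m plus an amplified urban term and heteroscedastic noise;
  **skt**, **sp**, **u10**, **v10**, **bsa**, **ndvi** with their obvious
  structures; static DEM, slope, lake/water/coast/buffer layers, population
  and imperviousness; **sza**/**daylength** computed deterministically from
  the affine row-to-latitude map (default band −24.1°…−23.3°);
* three pure-noise decoys.

True temperature is `intercept + Σ β_f · x_f + γ·((t2m − 20)/5)² + u(s) +
ε(s,t)` with β nonzero for the eight features a trained model should find
(t2m dominating at 0.75 °C/°C), `u` a Gaussian-kernel-smoothed spatial
field (sd 0.3 °C, range 2000 m), ε iid N(0, 0.5²) and γ = 0 by default
(γ = 1.5 turns on the non-linear term for forest-vs-linear comparisons).
Missingness mimics the ~10 % loss of real networks as station outage
blocks plus isolated days, masked to the exact target count, with
cloud-style blobs punched only into the optical stacks (lst, ndvi). All
randomness flows from one master seed through named substreams, so any
component regenerates independently and the whole dataset is bit-identical
under the same configuration.

What the synthetic world does **not** emulate: real radiometry and orbital
sampling, geodetic geometry, non-random missingness mechanisms, and
landscape complexity beyond one urban disc and one lake. Passing tests
demonstrate that the machinery is correct and that the pipeline recovers a
known process under realistic nuisance structure — not that any particular
accuracy will be achieved on real station networks.

## Numerical and design choices

* **Relative humidity** uses the Magnus saturation form with constants
  (6.112 hPa, 17.62, 243.12 °C); only the ratio of saturation pressures
  enters, so the leading constant cancels, and the constant set is an
  argument for users preferring another calibration. Values are clipped to
  [0, 100] as a guard, though consistent inputs (d2m ≤ t2m) never trigger
  it.
* **Day length** uses the standard declination/hour-angle model with the
  hour-angle argument clipped to [−1, 1] (poles resolve to 0 or 24 h).
* **Slope** uses central differences over four-connected neighbours (not
  Horn's eight-neighbour kernel), one-sided at edges and next to missing
  cells.
* **Grids** are flat metric planes: row 1 at the north edge, cell-centre
  sampling, half-open cell intervals — fixed conventions so geometry tests
  can be exact. Bilinear resampling clamps to edge centres inside the
  source extent (no overshoot) and propagates any missing stencil corner;
  nearest copies the containing cell; target centres outside the source
  extent go missing.
* **Temporal interpolation** is cell-wise linear between native slices,
  holding the nearest slice constant beyond the ends — no trend
  extrapolation at series boundaries.
* **Gap filling** for cloud-masked optical stacks iterates 3×3×3
  space–time neighbourhood means, then falls back to per-day spatial means
  and finally the global mean. It is a deliberately simple, dependency-free
  imputation; observed values are never altered.
* **Raster I/O** is plain text (long CSV plus a JSON header sidecar),
  chosen so datasets round-trip losslessly without binary format
  dependencies.

## Problem sizes and the recovery tests

The demonstration and acceptance runs use the default world — 48 stations
on a 20 × 20 half-km grid over 2015–2019 (≈79,000 observed station-days) —
with hyperparameters (300 trees, `sqrt`, depth 10), the lightest
combination of the stated grid: forest accuracy on this world is flat
across the grid while fit cost is not, and depth-15 forests would multiply
run time several-fold for indistinguishable metrics. Forward-selection
correctness is checked on ≤6-candidate worlds against an independent greedy
re-implementation; the forest-vs-linear ordering uses one year of the
default world with γ = 1.5.

One subtlety deserves record. In the coefficient-recovery test, naive OLS
standard errors — and station-clustered sandwich errors — understate the
true sampling variability of the linear baseline's coefficients. The
smooth spatial field `u(s)` acts as a spatially *correlated* station-level
disturbance, and the solar pair (sza, daylength) is so collinear over a
narrow latitude band (r ≈ −0.9998) that its coefficients are identified
mostly by small between-station contrasts — exactly the contrasts the field
perturbs; the fitted regression absorbs the field, so residual-based
estimators cannot see it. The test therefore compares estimates to truth
against the *exact* sampling covariance implied by the known generating
process: σ²I plus the spatial covariance of station field values, the
latter obtained by Monte Carlo over field realizations. Under that metric
the estimator is well calibrated (|z| ≲ 2.5 across seeds). This is a
statement about inference on synthetic truth; on real data no such oracle
exists, which is one more reason the package reports leave-location-out
skill rather than coefficient inference.

## Known limitations

Forest predictions compress extremes beyond the training range; spatial
skill is bounded by station coverage (the synthetic urban/rural imbalance
reproduces the familiar urban-better-than-rural accuracy gap); residual
spatial autocorrelation is not modelled (no spatially explicit learner);
and prediction uncertainty is not quantified — quantile forests would be
the natural extension. The t-test hold-out design yields a *harder*
external set by construction; its metrics should be read as conservative.
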