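---
title: "Methods: detecting groundwater yield subsidies and penalties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting groundwater yield subsidies and penalties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In humid rainfed cropland, a shallow water table can act on maize yields in
two opposite ways. Where the capillary fringe or the roots themselves can
reach groundwater, crops draw supplemental water exactly in the weeks when
rainfall fails — a *yield subsidy* relative to "free drainage" conditions in
which the water table is too deep to matter. Where the water table rises into
the root zone, oxygen stress and waterlogging cut yields — a *yield penalty*.
`gwyield` implements an inferential pipeline that estimates the depth
response curve from observational (or simulated) yield data, delineates the
subsidy and penalty zones, and quantifies how often and how much these
conditions matter.

The pipeline is: fit a bagged regression-tree surrogate of yield on July
depth-to-water plus weather, soil and soil-moisture covariates; summarise the
fitted model's depth response with a first-order accumulated local effects
(ALE) curve; read the free-drainage baseline, subsidy zone, optimum and
penalty threshold off that curve; then run companion experiments
(noise-attenuation, covariate-swap mechanism split, stability, prevalence
accounting) against the same machinery.

Because region-scale satellite yields and crop-model grids cannot ship with
a package, every stage is exercised against a *synthetic world* whose
groundwater effect is injected and therefore known exactly. All empirical
claims about the package are parameter-recovery claims: the tests inject an
effect, run the full pipeline, and check that the known quantities come back.

## The injected effect

`true_effect(depth, deficit, params)` is the ground truth of the synthetic
world, with `gw_effect_params()` defaults:

* a linear waterlogging penalty below `d_low` = 1.1 m
  (`penalty_slope` = 0.8 t/ha per metre shallower);
* a raised-cosine subsidy bump on [`d_low`, `d_high`] = [1.1 m, 2.5 m]
  peaking at `d_opt` = 1.5 m with amplitude `s_max` = 0.37 t/ha — the
  raised cosine is continuous with zero derivative at both zone edges and at
  the peak; the field evidence constrains only the zone boundaries and the
  optimum, so the smooth interpolant is a package choice;
* exactly zero at and beyond `d_high` (free drainage);
* the bump amplitude doubles (`drought_amplifier` = 2) when the July water
  deficit is below −150 mm: shallow groundwater is worth most when rain
  fails hardest. Wet Julys do not worsen the penalty
  (`wet_penalty_amplifier` fixed at 1).

## The synthetic world

`simulate_world(sim_config())` generates grid-cell-by-year records. Design
choices, each fixed once:

* **Water tables.** Site mean depth uniform on 0.3–6 m; an AR(1) annual
  anomaly (persistence 0.45, SD 0.25 m); a weather coupling of 0.6 m per
  100 mm of July deficit beyond the mean, so water tables fall substantially
  in dry years (the empirical depth–deficit correlation is negative). The
  coupling dominating the non-weather anomaly reflects
  persistence-dominated shallow aquifers whose growing-season decline
  tracks the climatic water balance; it is also what makes the stability
  phenomenon possible at all — a site at 1 m mean depth is pushed toward
  the 1.5 m optimum exactly in the years it is water-stressed.
  Depths truncate at 0.05 m and tiled cells (25%, tile depth 1 m) never
  report shallower than the tile depth. Monthly (May–August) depths are the
  July value plus a seasonal offset and month noise (SD 0.35 m).
* **Weather.** July deficit ~ Normal(−60, 70) mm with 60% of its variance
  shared regionally per year. This populates all four weather classes
  (wet ≈ 20%, normal ≈ 26%, dry ≈ 46%, very dry ≈ 9%). July VPD has a
  persistent site component (SD 0.3 kPa) and co-varies with the deficit.
* **Yield.** Base yield 11 t/ha plus a small AWC term, minus a concave
  drought loss `sens × (max(0, −50 − deficit)/100)²` that activates once
  the deficit passes −50 mm. `sens` scales with site VPD
  (`vpd_sens` = 1.2 per kPa): the same rainfall shortfall costs more where
  evaporative demand is high. Residual noise SD 0.7 t/ha. A panel of
  correlated nuisance covariates (June deficit, May precipitation, GDD,
  texture and organic-matter fractions, conductivity, topography, planting
  day) emulates the kind of variable set a real analysis screens; a few of
  them carry small real effects.
* **The capillary channel.** A share `1 − direct_share` (default 45%) of
  the subsidy operates through root-zone soil moisture. `sm_standard` holds
  top-down (rain/ET) moisture only; `sm_enhanced` adds the capillary
  increment `c_max × max(0, 1 − depth/capillary_reach)`. The reach defaults
  to `d_high` = 2.5 m: the fringe influences soil moisture up to about a
  metre above the water table and the maize root zone extends to roughly
  1.5 m, so a water table within 2.5 m of the surface can feed the root
  zone. `c_max` is calibrated so the median relative moisture boost over
  cells within reach matches `capillary_boost_median` (30.8%), and the
  soil-moisture yield coefficient is then set so that the coefficient times
  the increment at `d_opt` equals the indirect share of `s_max`. This makes
  the identity exact by construction: a surrogate conditioned on
  `sm_standard` attributes the whole effect to depth; one conditioned on
  `sm_enhanced` attributes only the direct share. With `direct_share = 1`
  the channel vanishes and the two moisture columns coincide.
* **Grains.** `"grid"` gives one record per cell-year. `"pixel"` attaches
  several persistent locations to each cell; each location's true depth is
  the cell depth plus a fixed local offset (SD 0.35 m), its yield is
  generated from that true depth, but the *recorded* depth is the coarse
  cell value. This built-in resolution mismatch is what the attenuation
  experiment studies.

What the generator does **not** emulate: spatial autocorrelation beyond the
cell, management variation, multi-crop rotation, measurement bias in
yields, price dynamics (constant price by default), trends. Passing tests
therefore demonstrate statistical correctness of the machinery under known
conditions, not robustness to every failure mode of real data.

## The surrogate

`fit_surrogate()` wraps a bagged regression-tree ensemble (ranger) with 100
trees, six variables per split and minimum node size 10 — hyperparameters
chosen to resist overfitting while leaving the ensemble flexible enough to
trace a sub-half-tonne effect; they are deliberately not tuned per run.
Performance is evaluated on out-of-bag samples; fits are bit-reproducible
given the seed and row order.

The default predictor panel has 10 columns (`world_predictors()`). The panel
width matters more than is obvious: with very few covariates and
`mtry = 6`, depth is available at almost every split and the estimated ALE
curve accumulates spurious depth structure (drift) in its deep tail; with
all 19 emulated columns, depth splits become so sparse that the recovered
bump attenuates to roughly half the injected amplitude at desk-scale n. Ten
columns balances the two failure modes; `extended_predictors()` exposes the
full panel for experiments on this trade-off.

`screen_groundwater_period()` reproduces the variable-screening step that
identifies July as the relevant groundwater time step: greedy forward
selection over the May/June/July/August/annual depth columns on out-of-bag
MSE, stopping when the best relative improvement falls below 1%. OOB error
is used rather than a holdout split because the candidate ranking is then
computed from every row, which at desk-scale n is the difference between a
stable and an unstable selection.

## The ALE estimator

`compute_ale()` is a from-scratch first-order accumulated local effects
implementation: quantile bins (default `k_bins = 40` — fine enough to
resolve a ~0.1 m zone boundary over a 0–6 m depth range), per-bin local
differences with all other covariates held at observed values, cumulative
accumulation, and centring at the count-weighted mean so effects read
relative to the population mean prediction. Duplicate quantile edges (heavy
ties, e.g. tile-drain depths) are merged with pooled counts. Local
conditioning is what keeps the estimator meaningful under correlated
predictors; partial dependence would evaluate covariate combinations that
never occur.

`bootstrap_ale()` adds a percentile 2.5/97.5% envelope across refits on
resampled data, evaluated on the point curve's bin edges. The resampling
unit is the grid cell (cluster bootstrap), not the row, because records of
one cell share a water-table history; row bootstraps understate
uncertainty. The production default is 500 resamples; tests and examples
use fewer.

## Zone delineation

`delineate()` turns a depth-ALE curve into the headline quantities. The
free-drainage plateau is found by scanning from the deep end; the baseline
is the count-weighted mean effect on the plateau; the optimum is the effect
argmax shallower than the plateau; the shallow zone edge is the baseline
crossing nearest the optimum (linear interpolation; when noise yields
several crossings the nearest is the conservative choice); the maximum
subsidy is the effect at the optimum minus the baseline, also as a percent
of mean yield.

Numerical choices that required care:

* **Slope estimation.** An estimated ALE curve carries accumulated
  (random-walk) noise: raw adjacent-edge slopes on a flat plateau routinely
  breach any sensible tolerance. Per-bin slopes are therefore count-weighted
  least-squares slopes over a *forward* (deep-side) window of `2 × smooth_bw`
  (default 1 m). A forward window leaves the estimate untouched by the
  subsidy limb while scanning from deep, avoiding the boundary bias of a
  centred kernel. With `smooth_bw = 0` the estimator reduces to adjacent
  differences, which recover a noise-free curve's boundaries exactly.
* **Drift bridging.** Long plateaus of estimated curves show diffuse drift
  whose local slopes exceed `slope_tol` = 0.02 t/ha/m even after
  windowing, while the genuine subsidy limb is a large localised rise with
  slopes several times higher. A two-phase scan separates them: phase 1
  finds the terminal run at a coarse tolerance (`coarse_tol` = 0.1
  t/ha/m) that drift does not breach; phase 2 refines the run's shallow
  boundary to the first bin flat at `slope_tol` proper. On a noise-free
  curve phase 2 lands on the exact flatness onset.
* **Detection.** A subsidy is declared only when the maximum subsidy
  exceeds `min_effect` = 0.02 t/ha and, when a bootstrap band is present,
  the band's lower envelope at the optimum clears the baseline. A curve
  with no qualifying plateau is flagged "no free-drainage baseline" rather
  than forced — this genuinely occurs for noisy curves and the attenuation
  experiment exploits the fallback described below.

`stratified_effects()` re-evaluates the all-sample surrogate's ALE within
weather-class strata on shared bin edges (one model, the stratification
affecting only which rows' local effects are accumulated) for the
class-wise curves. The drought-amplification ratio (very-dry : all-sample
maximum subsidy, expected near 2 under the default generator) is instead
computed from *size-matched refits*: one surrogate on the very-dry rows,
one on an equally sized random subsample of all rows. A pooled model
expresses the depth-by-deficit interaction only as far as the ensemble has
learned it, which pulls the re-evaluated contrast toward 1 at desk-scale
n; matching the refits' sample sizes makes their small-sample attenuation
comparable so it cancels in the ratio.

## Attenuation (regression dilution)

`inject_noise()` degrades the depth covariate to a target correlation r
with truth using the closed-form noise SD `sd(x) * sqrt(1/r² − 1)`, then
truncates at zero (logged). `run_attenuation_experiment()` refits the
surrogate on the noisy depth and re-measures the maximum subsidy. Because a
noisy curve typically loses its crisp plateau, the noisy subsidy is
measured against the *clean* run's plateau window — the same move the
observational analysis makes when a simulation curve lacks a clean
free-drainage transition. For a linear injected effect the shrinkage should
approach the classical errors-in-variables factor r², which the test suite
checks at r = 0.6 (factor 0.36) using the generator's linear-effect
variant and the count-weighted ALE slope.

## Mechanism split

`mechanism_split()` runs the depth analysis twice on the same data and
seed: run A conditions on `sm_standard` (total effect on depth), run B on
`sm_enhanced` (capillary channel absorbed by the covariate). The indirect
share is `1 − effect_B(d_opt)/effect_A(d_opt)` at run A's optimum, both
effects measured against run A's free-drainage window; shares are clipped
to [0, 1] and sum to one. The split is defined at the optimum because that
is the comparison point of interest; a curve-integrated variant would mix
zone edges where the two runs' curves are least distinguishable.

## Stability

`stability_analysis()` computes each location's interannual yield CV
(sample SD over mean, in percent), fits a surrogate of CV on location-level
covariates, and reads the CV–depth ALE overall and within terciles of
location-mean VPD (ties broken by location id; tercile curves are
per-tercile refits on shared bin edges). `stability_gap()` reads the curve
as window means around two reference depths, and
`stability_tercile_gaps()` gives the model-free windowed contrast straight
from the location table — the highest-powered per-draw estimate of the
tercile margin. The expected signal —
lower CV at subsidy-zone depths, more so where VPD is high — is emergent:
the generator never touches CV. It arises because the subsidy is
anti-correlated with the drought loss (amplified in very dry years, and
dry-year water-table deepening shifts shallow sites into the zone), so the
interannual spread compresses exactly where groundwater is accessible.
Yields are not detrended before the CV; the generator has no trend.

## Prevalence and accounting

`flag_conditions()` applies the delineated thresholds: penalty = depth
shallower than the zone's lower edge; access = depth within the closed
zone interval; dry / very dry = deficit below −50 / −150 mm; subsidy =
access AND dry (access alone is not a subsidy — groundwater only helps
when a deficit limits yield). Weather-class boundary conventions: −50 mm
is normal, −150 mm is dry, wet requires a strictly positive balance.
`monetary_impact()` values each flagged cell-year at production × price ×
rate, with default rates 1% (penalty cost), 3.4% (subsidy) and 7.8%
(very-dry subsidy); the stronger applicable rate replaces, never stacks.
Penalties are reported as positive costs.

## Problem sizes and reproducibility

The package's reference experiments (test suite and acceptance script) run
the zone-recovery pipeline at 2,000 cells × 20 years (40,000 records) over
10 seeds, and the companion experiments at 150–1,600 cells with 3–10 seeds
or replicates — sizes at which the recovery tolerances below hold while a
full run stays desk-scale. Expected recoveries under defaults: optimum
within ±0.2 m, zone bounds within ±0.3 m, maximum subsidy within ±25%
(seed medians); drought ratio in [1.6, 2.4]; direct share within ±0.15;
attenuation shrinkage within ±0.1 of r² for the linear variant.

Every random stage takes an explicit integer seed; `run_pipeline()` derives
per-stage child seeds from one master seed and writes a manifest with the
resolved configuration, every defaulted analysis parameter and an MD5 hash
per artifact, so identical config + seed reproduces byte-identical runs.

## Known limitations

* The delineation thresholds (`slope_tol`, `min_plateau_width`,
  `min_effect`, `dev_tol`) are free parameters of plot-reading, surfaced in
  the configuration and logged; different choices move zone bounds by a few
  bin widths.
* The recovered maximum subsidy is biased slightly low (tree-ensemble
  smoothing) and the drought amplifier inflates the all-sample curve by the
  very-dry share; both effects are visible in the recovery tolerances.
* The mechanism split inherits correlated-predictor leakage from the tree
  ensemble: at small n run B retains some indirect effect on depth,
  biasing the recovered direct share upward; the tolerance ±0.15 reflects
  desk-scale n.
* No SIMEX/deconvolution correction of attenuated estimates; the
  attenuation module quantifies dilution, it does not undo it. For the
  default bump-shaped effect, dilution is much stronger than the classical
  linear r² factor because measurement noise convolves the narrow bump
  flat; the r² closed form applies (and is tested) only for the generator's
  linear-effect variant.
* The stability tercile margin (stronger stabilisation where VPD is high)
  is present on average but rides on the handful of regional very-dry years
  in a 20-year draw; individual simulated draws can fail to show it, and
  the test suite's sign test reflects that honestly.
* County-style aggregation is available only as a mean-by-group utility on
  the simulated table; there is no spatial raster machinery.
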