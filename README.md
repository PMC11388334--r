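# gwyield

Shallow groundwater cuts both ways for rainfed maize. Where roots or the
capillary fringe can reach the water table, crops draw supplemental water in
exactly the weeks when rain fails — a **yield subsidy** relative to
free-drainage conditions. Where the water table rises into the root zone,
waterlogging imposes a **yield penalty**. `gwyield` is an R package for
detecting, delineating and pricing these effects from grid-cell-by-year
yield data, built for agroecosystem modellers and environmental
biostatisticians who want the full inferential chain in testable form.

## What it does

The core statistic is the **accumulated local effects (ALE)** curve of a
bagged regression-tree yield surrogate over July depth-to-water `d`:

* the surrogate predicts yield from `d` plus weather, soil and soil-moisture
  covariates (100 trees, 6 variables per split, node size 10, out-of-bag
  evaluation);
* the first-order ALE accumulates per-quantile-bin local differences
  `f(x: d = z_k) − f(x: d = z_{k−1})` and centres the curve at the mean
  prediction, which keeps it interpretable under correlated covariates;
* `delineate()` reads off the free-drainage plateau (baseline), the subsidy
  zone `[d_low, d_high]`, the optimum `d_opt`, the maximum subsidy
  (t/ha and % of mean yield) and the penalty threshold.

Around that core: cluster-bootstrap confidence bands, weather-class
stratification (wet / normal / dry / very dry at 0 / −50 / −150 mm of July
precipitation − PET), a regression-dilution experiment for noisy water-table
measurements, a covariate-swap decomposition of the subsidy into direct
root-uptake vs capillary soil-moisture channels, an interannual
yield-stability (CV) analysis by VPD tercile, and prevalence + monetary
accounting of subsidy/penalty conditions.

Everything runs against a synthetic grid-cell world
(`simulate_world()`) with a known injected effect, so every stage is
verifiable by parameter recovery. See the methods vignette
(`vignettes/groundwater-yield-methods.Rmd`) for the model, assumptions and
numerical choices.

## Worked example

```r
library(gwyield)

cfg   <- sim_config(n_cells = 2000, n_years = 20, seed = 11)
world <- simulate_world(cfg)                    # 40,000 cell-year records
fit   <- fit_surrogate(world, surrogate_spec(world_predictors(), seed = 111))
curve <- compute_ale(fit$predict, world, "wt_depth_jul", k_bins = 40)
zones <- delineate(curve, mean_yield = mean(world$yield))
zones
#> <zone_report>
#>   baseline: 0.00046 t/ha | free drainage from 2.27 m
#>   subsidy zone: 1.01 - 2.27 m, optimum 1.55 m
#>   max subsidy: 0.303 t/ha (2.8% of mean yield)
```

The world was generated with a subsidy zone of 1.1–2.5 m, an optimum at
1.5 m and a peak subsidy of 0.37 t/ha; the fitted pipeline recovers the
zone edges within a few bin widths and the peak within the tree-ensemble's
smoothing bias. `plot_ale(curve)` draws the curve with its rug;
`flag_conditions()` + `tally_prevalence()` + `monetary_impact()` turn the
zone report into per-cell condition counts and dollar values;
`run_pipeline(cfg, out_dir = "run1")` executes every stage into an
auditable run directory with a manifest.

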