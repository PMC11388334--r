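small_cfg <- function(...) sim_config(n_cells = 250, n_years = 10, seed = 42, ...)

test_that("the injected effect matches its piecewise definition", {
  p <- gw_effect_params() # d_low 1.1, d_opt 1.5, d_high 2.5, s_max 0.37
  # free drainage: identically zero at and beyond d_high
  expect_equal(true_effect(c(2.5, 3, 6), -80, p), c(0, 0, 0))
  # optimum under very dry conditions: exactly amplifier x s_max
  expect_equal(true_effect(1.5, -200, p), 2 * p$s_max)
  expect_equal(true_effect(1.5, -80, p), p$s_max)
  # hand evaluation of the linear penalty: depth 0.6 -> -slope * 0.5
  expect_equal(true_effect(0.6, -80, p), -p$penalty_slope * 0.5)
  # continuity at the zone edges
  expect_lt(abs(true_effect(1.1 - 1e-9, -80, p) - true_effect(1.1 + 1e-9, -80, p)), 1e-6)
  expect_lt(abs(true_effect(2.5 - 1e-9, -80, p)), 1e-6)
  # maximum over depth is s_max, attained at d_opt
  grid <- seq(0, 4, by = 0.001)
  eff <- true_effect(grid, -80, p)
  expect_equal(max(eff), p$s_max)
  expect_equal(grid[which.max(eff)], p$d_opt)
  expect_error(true_effect(-0.5, 0, p), ">= 0")
})

test_that("parameter validation rejects degenerate configurations", {
  expect_error(gw_effect_params(drought_amplifier = 0.5), "shrink under drought")
  expect_error(gw_effect_params(d_low = 2, d_opt = 1.5), "d_low < d_opt")
  expect_error(sim_config(n_cells = 0), "positive")
  expect_error(sim_config(wt_ar1 = 1), "wt_ar1")
  expect_error(sim_config(price = -2), "price")
})

test_that("simulation is bit-reproducible under a fixed seed and varies across seeds", {
  w1 <- simulate_world(small_cfg())
  w2 <- simulate_world(small_cfg())
  expect_identical(as.data.frame(w1), as.data.frame(w2))
  w3 <- simulate_world(small_cfg(), seed = 43)
  expect_false(isTRUE(all.equal(w1$yield, w3$yield)))
})

test_that("generated worlds satisfy the structural invariants", {
  w <- simulate_world(small_cfg())
  cfg <- attr(w, "config")
  expect_equal(nrow(w), 250 * 10)
  expect_true(all(w$yield > 0))
  expect_true(all(w$wt_depth_jul >= 0.05))
  # every weather class populated at default settings
  expect_true(all(table(w$weather_class) > 0))
  # dry years lower the water table
  expect_lt(cor(w$wt_depth_jul, w$deficit_july), 0)
  # tiled cells never shallower than tile depth
  expect_true(all(w$wt_depth_jul[w$tiled] >= cfg$tile_depth - 1e-9))
  # capillary channel: enhanced >= standard, strictly within reach only
  expect_true(all(w$sm_enhanced >= w$sm_standard))
  inside <- w$depth_true < cfg$capillary_reach
  expect_true(all(w$sm_enhanced[inside] > w$sm_standard[inside]))
  expect_true(all(w$sm_enhanced[!inside] == w$sm_standard[!inside]))
  # recorded truth: exact zero at free drainage
  expect_true(all(w$true_effect[w$depth_true >= cfg$gw_effect$d_high] == 0))
  expect_equal(w$true_effect,
               true_effect(w$depth_true, w$deficit_july, cfg$gw_effect))
})

test_that("binned yields reproduce the injected bump and penalty before any model", {
  w <- simulate_world(sim_config(n_cells = 1500, n_years = 15, seed = 7))
  deep <- w$depth_true > 2.6 & w$depth_true < 6
  peak <- w$depth_true > 1.3 & w$depth_true < 1.7
  shallow <- w$depth_true < 0.6
  # subsidy visible in raw binned yields (sampling error well below s_max)
  expect_gt(mean(w$yield[peak]) - mean(w$yield[deep]), 0.15)
  # penalty visible at the shallow end
  expect_lt(mean(w$yield[shallow]) - mean(w$yield[deep]), -0.1)
  # binned profile tracks the injected curve shape
  bins <- cut(w$depth_true, seq(0, 4, by = 0.25))
  keep <- !is.na(bins)
  prof <- tapply(w$yield[keep], bins[keep], mean)
  truth <- tapply(w$true_effect[keep], bins[keep], mean)
  ok <- !is.na(prof)
  expect_gt(cor(prof[ok], truth[ok]), 0.8)
})

test_that("a null effect leaves recorded truth at zero everywhere", {
  w <- simulate_world(small_cfg(
    gw_effect = gw_effect_params(s_max = 0, penalty_slope = 0)))
  expect_true(all(w$true_effect == 0))
  expect_identical(attr(w, "c_max"), 0)
})

test_that("pixel grain shares the cell depth but varies truth within cells", {
  w <- simulate_world(sim_config(n_cells = 60, n_years = 6, grain = "pixel",
                                 pixels_per_cell = 5, seed = 9))
  expect_equal(nrow(w), 60 * 6 * 5)
  expect_equal(dplyr::n_distinct(w$location_id), 300)
  one <- w[w$cell_id == 1 & w$year == 1, ]
  # recorded (observable) depth is the coarse cell value
  expect_equal(length(unique(one$wt_depth_jul)), 1)
  # but the truth differs by pixel
  expect_gt(dplyr::n_distinct(one$depth_true), 1)
  # the persistent pixel offset is the same in every year
  locs <- w[w$location_id == one$location_id[2], ]
  offs <- locs$depth_true - locs$wt_depth_jul
  expect_lt(diff(range(offs[locs$depth_true > 0.05 + 1e-9])), 1e-9)
})

test_that("capillary calibration honours direct_share boundaries", {
  # direct_share = 1: no capillary channel at all
  w1 <- simulate_world(small_cfg(gw_effect = gw_effect_params(direct_share = 1)))
  expect_identical(attr(w1, "c_max"), 0)
  expect_equal(w1$sm_enhanced, w1$sm_standard)
  # default calibration reproduces the target median boost within reach
  w <- simulate_world(sim_config(n_cells = 600, n_years = 12, seed = 5))
  boost <- capillary_boost_summary(w)
  expect_lt(abs(boost$median - 30.8), 3)
  expect_gte(boost$iqr[["q25"]], 0)
})

test_that("worlds round-trip through the run-directory writers", {
  w <- simulate_world(sim_config(n_cells = 40, n_years = 4, seed = 3))
  dir <- withr::local_tempdir()
  write_world(w, dir)
  rec <- readr::read_csv(file.path(dir, "records.csv"), show_col_types = FALSE)
  expect_equal(nrow(rec), nrow(w))
  expect_equal(rec$yield, w$yield)
  expect_equal(rec$wt_depth_jul, w$wt_depth_jul)
  tru <- readr::read_csv(file.path(dir, "truth.csv"), show_col_types = FALSE)
  expect_equal(tru$true_effect, w$true_effect)
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  expect_equal(cfg$config$n_cells, 40)
  expect_equal(cfg$config$gw_effect$d_opt, 1.5)
})
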