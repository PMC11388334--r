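test_that("a noise-free bump-plus-tail curve is delineated exactly", {
  curve <- exact_zone_curve() # raised cosine on [1.1, 2.5], peak 1.5, flat tail
  z <- delineate(curve, mean_yield = 10.8, smooth_bw = 0)
  expect_true(z$detected)
  expect_equal(z$subsidy_low, 1.1, tolerance = 1e-8)
  expect_equal(z$d_opt, 1.5, tolerance = 1e-8)
  expect_equal(z$d_free, 2.5, tolerance = 1e-8)
  expect_equal(z$subsidy_high, z$d_free)
  expect_equal(z$penalty_threshold, z$subsidy_low)
  expect_equal(z$max_subsidy, 0.37, tolerance = 1e-8)
  # percent magnitude is exactly t/ha over mean yield
  expect_equal(z$max_subsidy_pct, z$max_subsidy / 10.8 * 100)
  # the penalty at the mean within-zone depth is positive
  expect_gt(as.numeric(z$penalty_at_mean_depth), 0)
})

test_that("an identically-zero curve yields no subsidy and baseline zero", {
  edges <- seq(0, 4, by = 0.1)
  curve <- gwyield:::new_ale_curve(edges, rep(0, length(edges)),
                                   rep(20L, length(edges) - 1L),
                                   "wt_depth_jul", 0)
  z <- delineate(curve, smooth_bw = 0)
  expect_false(z$detected)
  expect_match(z$flags, "no subsidy")
  expect_equal(z$baseline_effect, 0)
})

test_that("delineation is invariant to vertical shifts of the curve", {
  curve <- exact_zone_curve()
  shifted <- curve
  shifted$effect <- curve$effect + 0.5
  z1 <- delineate(curve, smooth_bw = 0)
  z2 <- delineate(shifted, smooth_bw = 0)
  expect_equal(z2$subsidy_low, z1$subsidy_low)
  expect_equal(z2$d_opt, z1$d_opt)
  expect_equal(z2$d_free, z1$d_free)
  expect_equal(z2$max_subsidy, z1$max_subsidy)
  expect_equal(z2$baseline_effect, z1$baseline_effect + 0.5)
})

test_that("with multiple baseline crossings the one nearest the optimum wins", {
  edges <- seq(0, 4, by = 0.05)
  eff <- true_effect(edges, -60, gw_effect_params(penalty_slope = 0))
  # a shallow spurious excursion above baseline, separated from the zone
  eff[edges >= 0.3 & edges <= 0.5] <- 0.05
  eff[edges > 0.5 & edges < 1.1] <- -0.03
  curve <- gwyield:::new_ale_curve(edges, eff, rep(30L, length(edges) - 1L),
                                   "wt_depth_jul", 0)
  z <- delineate(curve, smooth_bw = 0)
  # crossing between 1.05 and 1.1 (effect rises from -0.03 through 0), not 0.5
  expect_gt(z$subsidy_low, 1.0)
  expect_lt(z$subsidy_low, 1.15)
})

test_that("curves without a flat tail report no free-drainage baseline", {
  edges <- seq(0, 4, by = 0.1)
  curve <- gwyield:::new_ale_curve(edges, 0.2 * edges,
                                   rep(20L, length(edges) - 1L),
                                   "wt_depth_jul", 0)
  z <- delineate(curve, smooth_bw = 0)
  expect_false(z$detected)
  expect_match(z$flags, "no free-drainage baseline")
  expect_true(is.na(z$d_free))
  expect_error(delineate(gwyield:::new_ale_curve(1:5, rep(0, 5), rep(1L, 4),
                                                 "x", 0)), "10 edges")
})

test_that("a bootstrap band containing the baseline suppresses detection", {
  curve <- exact_zone_curve()
  curve$band_low <- curve$effect - 0.5 # wide band: straddles the baseline
  curve$band_high <- curve$effect + 0.5
  z <- delineate(curve, smooth_bw = 0)
  expect_false(z$detected)
  # a tight band clears the baseline and restores detection with a CI
  curve$band_low <- curve$effect - 0.01
  curve$band_high <- curve$effect + 0.01
  z2 <- delineate(curve, smooth_bw = 0)
  expect_true(z2$detected)
  expect_equal(unname(z2$max_subsidy_ci[1]), z2$max_subsidy - 0.01,
               tolerance = 1e-8)
})

test_that("zone reports serialise to JSON", {
  z <- delineate(exact_zone_curve(), mean_yield = 10.8, smooth_bw = 0)
  path <- withr::local_tempfile(fileext = ".json")
  write_zone_report(z, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$d_opt, z$d_opt)
  expect_equal(back$subsidy_low, z$subsidy_low)
  expect_null(back$curve)
})
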