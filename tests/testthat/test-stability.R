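px_world <- function(seed = 21) {
  simulate_world(sim_config(n_cells = 300, n_years = 10, grain = "pixel",
                            pixels_per_cell = 3, seed = seed))
}

test_that("per-location CVs equal the metrics-module definition exactly", {
  w <- px_world()
  st <- stability_analysis(w, seed = 1)
  loc <- st$locations
  # recompute one location by hand through coefficient_of_variation()
  for (id in loc$location_id[c(1, 50, 200)]) {
    y <- w$yield[w$location_id == id]
    expect_equal(loc$cv[loc$location_id == id], coefficient_of_variation(y))
  }
})

test_that("VPD terciles partition locations nearly evenly and deterministically", {
  w <- px_world()
  st1 <- stability_analysis(w, seed = 1)
  st2 <- stability_analysis(w, seed = 1)
  sizes <- table(st1$locations$vpd_tercile)
  expect_length(sizes, 3)
  expect_lte(diff(range(sizes)), 2)
  expect_identical(st1$locations$vpd_tercile, st2$locations$vpd_tercile)
})

test_that("locations with too few years are dropped with a count", {
  w <- px_world()
  drop_ids <- unique(w$location_id)[1:10]
  w2 <- w[!(w$location_id %in% drop_ids & w$year > 2), ]
  expect_message(st <- stability_analysis(w2, min_years = 5, seed = 1),
                 "10 locations dropped")
  expect_false(any(drop_ids %in% st$locations$location_id))
})

test_that("tercile curves share the all-location bin edges", {
  w <- px_world()
  st <- stability_analysis(w, seed = 1)
  expect_named(st$curves_tercile, c("low", "mid", "high"))
  for (cv in st$curves_tercile) {
    expect_equal(cv$edges, st$curve_all$edges)
  }
  # CV is in percent: all-location curve is centred around zero
  mide <- (head(st$curve_all$effect, -1) + tail(st$curve_all$effect, -1)) / 2
  expect_lt(abs(sum(st$curve_all$counts * mide) / sum(st$curve_all$counts)), 1e-8)
})

test_that("the CV-depth gap needs the injected subsidy: null worlds fall below matched signal worlds", {
  for (s in 41:43) {
    null_cfg <- sim_config(n_cells = 600, n_years = 15, grain = "pixel",
                           pixels_per_cell = 3, seed = s,
                           gw_effect = gw_effect_params(s_max = 0,
                                                        penalty_slope = 0))
    sig_cfg <- sim_config(n_cells = 600, n_years = 15, grain = "pixel",
                          pixels_per_cell = 3, seed = s)
    g_null <- stability_gap(suppressWarnings(
      stability_analysis(simulate_world(null_cfg), seed = 2))$curve_all)
    g_sig <- stability_gap(suppressWarnings(
      stability_analysis(simulate_world(sig_cfg), seed = 2))$curve_all)
    expect_gt(g_sig, g_null)
  }
})
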