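make_flag_fixture <- function() {
  tibble::tibble(
    cell_id = c(1, 1, 2, 2, 3, 3),
    year = c(1, 2, 1, 2, 1, 2),
    wt_depth_jul = c(1.8, 0.9, 2.5, 3.4, 1.2, 2.0),
    deficit_july = c(-80, -200, -80, -30, -160, 10),
    production = c(1000, 800, 1200, 900, 1000, 1100),
    price = c(150, 150, 150, 150, 150, 150)
  )
}

test_that("condition flags follow the zone and deficit thresholds", {
  fx <- make_flag_fixture()
  fl <- flag_conditions(fx, subsidy_low = 1.1, subsidy_high = 2.5)
  # depth 1.8 m, deficit -80: access and dry -> subsidy, not strong
  expect_true(fl$subsidy[1]); expect_false(fl$strong_subsidy[1])
  # depth 0.9 m: penalty regardless of deficit, never subsidy
  expect_true(fl$penalty[2]); expect_false(fl$subsidy[2])
  # depth 2.5 m exactly: access (closed upper bound)
  expect_true(fl$access[3])
  # depth 3.4 m: free drainage, nothing applies
  expect_false(fl$access[4] || fl$penalty[4])
  # access + very dry -> strong subsidy
  expect_true(fl$strong_subsidy[5])
  # wet year in zone: access but no subsidy
  expect_true(fl$access[6]); expect_false(fl$subsidy[6])
  # penalty and access are mutually exclusive everywhere
  expect_false(any(fl$penalty & fl$access))
})

test_that("flags require thresholds and reject incomplete rows", {
  fx <- make_flag_fixture()
  expect_error(flag_conditions(fx), "bounds required")
  fx$wt_depth_jul[2] <- NA
  expect_message(
    fl <- flag_conditions(fx, subsidy_low = 1.1, subsidy_high = 2.5),
    "1 rows")
  expect_equal(nrow(fl), 5)
})

test_that("tallies match brute-force enumeration on a 3x2 toy table", {
  fx <- make_flag_fixture()
  fl <- flag_conditions(fx, subsidy_low = 1.1, subsidy_high = 2.5)
  tl <- tally_prevalence(fl)
  # hand tally: cell 1 = rows (1.8,-80),(0.9,-200); cell 2 = (2.5,-80),(3.4,-30);
  # cell 3 = (1.2,-160),(2.0,10)
  expect_equal(tl$per_cell$access_years, c(1, 1, 2))
  expect_equal(tl$per_cell$penalty_years, c(1, 0, 0))
  expect_equal(tl$per_cell$dry_years, c(2, 1, 1))
  expect_equal(tl$per_cell$very_dry_years, c(1, 0, 1))
  expect_equal(tl$per_cell$subsidy_years, c(1, 1, 1))
  expect_equal(tl$per_cell$strong_subsidy_years, c(0, 0, 1))
  # set-intersection bounds
  expect_true(all(tl$per_cell$subsidy_years <=
                    pmin(tl$per_cell$access_years, tl$per_cell$dry_years)))
  expect_true(all(tl$per_cell$strong_subsidy_years <= tl$per_cell$subsidy_years))
  # regional fractions over 6 cell-years
  expect_equal(unname(tl$regional[["subsidy"]]), 3 / 6)
  # permutation invariance
  fl2 <- fl[sample(nrow(fl)), ]
  tl2 <- tally_prevalence(fl2)
  expect_equal(tl2$per_cell, tl$per_cell)
  expect_equal(tl2$regional, tl$regional)
})

test_that("all-false flags tally to zero", {
  fx <- make_flag_fixture()
  fx$wt_depth_jul <- 5
  fx$deficit_july <- 20
  tl <- tally_prevalence(flag_conditions(fx, subsidy_low = 1.1, subsidy_high = 2.5))
  expect_true(all(tl$per_cell$subsidy_years == 0))
  expect_true(all(tl$regional == 0))
})

test_that("monetary accounting is exact, linear and rate-exclusive", {
  fx <- make_flag_fixture()
  fl <- flag_conditions(fx, subsidy_low = 1.1, subsidy_high = 2.5)
  mon <- monetary_impact(fl)
  # row 1: 1000 t x $150 x 3.4% = $5,100 (ordinary subsidy)
  # row 5: 1000 t x $150 x 7.8% = $11,700 (strong rate replaces, never stacks)
  # row 3: 1200 t x $150 x 3.4% = $6,120
  expect_equal(mon$total_subsidy_value, 5100 + 11700 + 6120)
  # row 2: penalty cost 800 x 150 x 1% = $1,200, reported positive
  expect_equal(mon$total_penalty_cost, 1200)
  expect_equal(mon$net_value, mon$total_subsidy_value - mon$total_penalty_cost)
  # additivity over years
  expect_equal(sum(mon$annual$subsidy_value), mon$total_subsidy_value)
  # doubling prices doubles dollar totals
  fl2 <- fl; fl2$price <- fl2$price * 2
  expect_equal(monetary_impact(fl2)$total_subsidy_value,
               2 * mon$total_subsidy_value)
  # zero production -> zero dollars
  fl3 <- fl; fl3$production <- 0
  expect_equal(monetary_impact(fl3)$total_subsidy_value, 0)
  # zero rates -> zero dollars regardless of flags
  mon0 <- monetary_impact(fl, effect_pcts = c(penalty = 0, subsidy = 0,
                                              strong_subsidy = 0))
  expect_equal(mon0$net_value, 0)
  expect_error(monetary_impact(dplyr::mutate(fl, price = -1)), "negative")
})
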