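test_that("a predictor the model ignores has identically zero effect", {
  dat <- random_table(80, seed = 1)
  f <- function(d) 2 + 3 * d$x2
  curve <- compute_ale(f, dat, "x1", k_bins = 8)
  expect_equal(curve$effect, rep(0, length(curve$edges)))
  expect_equal(sum(curve$counts), nrow(dat))
})

test_that("a linear model's ALE lies on the coefficient line to machine precision", {
  dat <- random_table(150, seed = 2)
  b <- -1.37
  f <- function(d) 4 + b * d$x1 + 0.8 * d$x2 # x1, x2 correlated by design
  curve <- compute_ale(f, dat, "x1", k_bins = 12)
  # slope between every pair of edges equals b
  expect_equal(diff(curve$effect) / diff(curve$edges),
               rep(b, length(curve$edges) - 1), tolerance = 1e-12)
  expect_equal(ale_slope(curve), b, tolerance = 1e-10)
})

test_that("curves are centred: count-weighted midpoint mean is zero", {
  dat <- random_table(200, seed = 3)
  f <- function(d) d$x1^2 - d$x1 * d$x2
  curve <- compute_ale(f, dat, "x1", k_bins = 10)
  mide <- (head(curve$effect, -1) + tail(curve$effect, -1)) / 2
  expect_lt(abs(sum(curve$counts * mide) / sum(curve$counts)), 1e-8)
  # adding a constant to the model leaves the curve unchanged
  curve2 <- compute_ale(function(d) f(d) + 42, dat, "x1", k_bins = 10)
  expect_equal(curve2$effect, curve$effect)
})

test_that("ALE matches the independent brute-force oracle (quadratic, n = 12)", {
  dat <- random_table(12, seed = 4)
  f <- function(d) 1 + 0.5 * d$x1^2 + d$x2
  got <- compute_ale(f, dat, "x1", k_bins = 3)
  want <- naive_ale(f, dat, "x1", k_bins = 3)
  expect_equal(got$edges, want$edges, tolerance = 1e-12)
  expect_equal(got$effect, want$effect, tolerance = 1e-10)
  expect_equal(got$counts, want$counts)
})

test_that("additive components are recovered under strong predictor correlation", {
  withr::with_seed(9, {
    z <- rnorm(300)
    dat <- tibble::tibble(x1 = z + rnorm(300, sd = 0.45), # rho ~ 0.9
                          x2 = z + rnorm(300, sd = 0.45))
  })
  g1 <- function(x) sin(2 * x)
  g2 <- function(x) 0.5 * x^3
  f <- function(d) g1(d$x1) + g2(d$x2)
  c1 <- compute_ale(f, dat, "x1", k_bins = 15)
  # recovered up to an additive constant, exactly (additive model)
  resid <- c1$effect - g1(c1$edges)
  expect_lt(diff(range(resid)), 1e-10)
  c2 <- compute_ale(f, dat, "x2", k_bins = 15)
  expect_lt(diff(range(c2$effect - g2(c2$edges))), 1e-10)
})

test_that("degenerate features are rejected and heavy ties are merged", {
  dat <- tibble::tibble(x1 = rep(1, 30), x2 = rnorm(30))
  expect_error(compute_ale(function(d) d$x2, dat, "x1", k_bins = 5), "constant")
  dat2 <- tibble::tibble(x1 = c(rep(0, 25), 1:5), x2 = rnorm(30))
  expect_warning(curve <- compute_ale(function(d) d$x1, dat2, "x1", k_bins = 10),
                 "merged")
  expect_equal(sum(curve$counts), 30)
  expect_true(all(diff(curve$edges) > 0))
})

test_that("interpolation and fixed-edge evaluation behave", {
  dat <- random_table(100, seed = 5)
  f <- function(d) 2 * d$x1
  curve <- compute_ale(f, dat, "x1", k_bins = 10)
  mid <- mean(curve$edges[5:6])
  expect_equal(ale_at(curve, mid),
               mean(curve$effect[5:6]), tolerance = 1e-12)
  # constant extrapolation beyond the range
  expect_equal(ale_at(curve, max(curve$edges) + 10), tail(curve$effect, 1))
  # re-evaluation on supplied edges keeps the grid
  curve2 <- compute_ale(f, dat[1:40, ], "x1", edges = curve$edges)
  expect_equal(curve2$edges, curve$edges)
  expect_equal(sum(curve2$counts), 40)
})

test_that("cluster bootstrap collapses for a single cluster and orders bands", {
  withr::with_seed(7, {
    dat <- tibble::tibble(cell_id = 1, x1 = rnorm(60), x2 = rnorm(60))
    dat$y <- 2 * dat$x1 + rnorm(60, sd = 0.1)
  })
  factory <- function(d) {
    fit <- lm(y ~ x1 + x2, data = d)
    function(nd) unname(predict(fit, nd))
  }
  curve <- bootstrap_ale(factory, dat, "x1", k_bins = 5, n_boot = 4, seed = 1)
  # resampling the only cluster always returns the full data: band collapses
  expect_equal(curve$band_low, curve$effect, tolerance = 1e-10)
  expect_equal(curve$band_high, curve$effect, tolerance = 1e-10)

  withr::with_seed(8, {
    dat2 <- tibble::tibble(cell_id = rep(1:12, each = 8),
                           x1 = rnorm(96), x2 = rnorm(96))
    dat2$y <- 1.5 * dat2$x1 + 0.3 * dat2$x2 + rnorm(96, sd = 0.3)
  })
  curve2 <- bootstrap_ale(factory, dat2, "x1", k_bins = 6, n_boot = 20, seed = 2)
  expect_true(all(curve2$band_low <= curve2$effect + 1e-12))
  expect_true(all(curve2$band_high >= curve2$effect - 1e-12))
})

test_that("bootstrap fails hard when too many refits fail", {
  dat <- tibble::tibble(cell_id = rep(1:10, each = 5), x1 = rnorm(50))
  broken <- function(d) stop("refit broke")
  expect_error(
    suppressWarnings(bootstrap_ale(broken, dat, "x1", k_bins = 4, n_boot = 5,
                                   seed = 1)))
})
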