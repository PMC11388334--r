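#' Groundwater effect parameters
#'
#' Parameterises the true (injected) groundwater-yield effect of the synthetic
#' world. The effect is a piecewise-smooth function of July depth-to-water
#' `d` (m, positive downward, 0 = water table at the surface):
#'
#' * a linear waterlogging penalty `-penalty_slope * (d_low - d)` for
#'   `d < d_low`;
#' * a raised-cosine subsidy bump on `[d_low, d_high]` peaking at `d_opt`
#'   with amplitude `s_max` (continuous, zero-derivative at both edges and at
#'   the peak);
#' * exactly zero for `d >= d_high` ("free drainage": the water table is too
#'   deep to supply the root zone).
#'
#' In very dry Julys (water deficit < -150 mm) the bump amplitude is
#' multiplied by `drought_amplifier`; a shallow water table is worth most
#' exactly when rain fails. Wet Julys do not worsen the penalty
#' (`wet_penalty_amplifier` is fixed at 1). `direct_share` is the proportion
#' of the subsidy delivered by direct root uptake from the saturated zone;
#' the remainder is delivered through capillary rise into the root-zone soil
#' moisture and is what the enhanced soil-moisture covariate can explain.
#'
#' @param d_low Shallow edge of the subsidy zone (m); also the penalty onset.
#' @param d_opt Depth of maximum subsidy (m).
#' @param d_high Deep edge of the subsidy zone / free-drainage onset (m).
#' @param s_max Maximum subsidy at `d_opt` under non-very-dry conditions (t/ha).
#' @param penalty_slope Yield loss per metre shallower than `d_low` (t/ha/m).
#' @param drought_amplifier Multiplier on the bump when deficit < -150 mm;
#'   must be >= 1 (the subsidy must not shrink under drought).
#' @param wet_penalty_amplifier Multiplier on the penalty in wet Julys; fixed
#'   default 1 (wet Julys do not worsen the penalty).
#' @param direct_share Proportion in \[0, 1\] of the subsidy attributable to
#'   direct root uptake.
#' @return An object of class `gw_effect_params`.
#' @export
gw_effect_params <- function(d_low = 1.1, d_opt = 1.5, d_high = 2.5,
                             s_max = 0.37, penalty_slope = 0.8,
                             drought_amplifier = 2,
                             wet_penalty_amplifier = 1,
                             direct_share = 0.55) {
  if (!(0 < d_low && d_low < d_opt && d_opt < d_high)) {
    stop("gw_effect_params(): need 0 < d_low < d_opt < d_high", call. = FALSE)
  }
  if (s_max < 0) stop("gw_effect_params(): s_max must be >= 0", call. = FALSE)
  if (penalty_slope < 0) stop("gw_effect_params(): penalty_slope must be >= 0", call. = FALSE)
  if (drought_amplifier < 1) {
    stop("gw_effect_params(): drought_amplifier must be >= 1 ",
         "(the subsidy must not shrink under drought)", call. = FALSE)
  }
  if (direct_share < 0 || direct_share > 1) {
    stop("gw_effect_params(): direct_share must be in [0, 1]", call. = FALSE)
  }
  structure(list(d_low = d_low, d_opt = d_opt, d_high = d_high, s_max = s_max,
                 penalty_slope = penalty_slope,
                 drought_amplifier = drought_amplifier,
                 wet_penalty_amplifier = wet_penalty_amplifier,
                 direct_share = direct_share),
            class = "gw_effect_params")
}

# subsidy bump only (no penalty, no drought amplifier), in [0, s_max]
gw_bump <- function(depth, params) {
  p <- params
  out <- numeric(length(depth))
  up <- depth >= p$d_low & depth <= p$d_opt
  dn <- depth > p$d_opt & depth < p$d_high
  out[up] <- p$s_max * 0.5 * (1 - cos(pi * (depth[up] - p$d_low) / (p$d_opt - p$d_low)))
  out[dn] <- p$s_max * 0.5 * (1 + cos(pi * (depth[dn] - p$d_opt) / (p$d_high - p$d_opt)))
  out
}

#' True injected groundwater-yield effect
#'
#' Evaluates the generator's ground-truth effect (t/ha) at given depths and
#' July water deficits. See [gw_effect_params()] for the functional form.
#' This is a total function: any non-negative depth and finite deficit map to
#' a value; depths at or beyond `d_high` map to exactly 0.
#'
#' @param depth Depth to water (m, >= 0), vectorised.
#' @param deficit July water deficit (mm), vectorised (recycled).
#' @param params A [gw_effect_params()] object.
#' @return Effect in t/ha (positive = subsidy, negative = penalty).
#' @examples
#' p <- gw_effect_params()
#' true_effect(3.0, -80, p)          # 0: free drainage
#' true_effect(1.5, -200, p)         # 2 * s_max: very-dry amplification
#' @export
true_effect <- function(depth, deficit, params) {
  stopifnot(inherits(params, "gw_effect_params"))
  if (any(depth < 0)) stop("true_effect(): depth must be >= 0", call. = FALSE)
  n <- max(length(depth), length(deficit))
  depth <- rep_len(depth, n); deficit <- rep_len(deficit, n)
  amp <- ifelse(deficit < -150, params$drought_amplifier, 1)
  pen <- -params$penalty_slope * pmax(0, params$d_low - depth) *
    params$wet_penalty_amplifier
  amp * gw_bump(depth, params) + pen
}

#' Synthetic-world configuration
#'
#' Full parameterisation of the synthetic grid-cell-by-year world. The
#' defaults define the package's reference study conditions: site-level mean
#' depth-to-water uniform on 0.3--6 m, an AR(1) annual water-table anomaly
#' that deepens in dry years, a July water-deficit distribution spanning all
#' four weather classes, tile drainage capping shallow water tables in a
#' quarter of cells, a concave base-yield response to water deficit whose
#' drought sensitivity grows with vapour-pressure deficit, and the injected
#' groundwater effect of [gw_effect_params()].
#'
#' Two observation grains are available. `"grid"` yields one record per
#' cell-year (the crop-model grid). `"pixel"` emulates satellite yield pixels:
#' several locations per cell, each with a persistent local depth offset and
#' its own yield noise, while the *recorded* `wt_depth_jul` is the coarse
#' cell value — the built-in spatial mismatch that the attenuation analysis
#' studies.
#'
#' @param n_cells,n_years Number of grid cells and years.
#' @param seed Integer seed; identical `(config, seed)` gives a bit-identical
#'   table.
#' @param wt_mean_range Range (m) of site-level mean depth-to-water.
#' @param wt_ar1 Year-to-year persistence of the water-table anomaly, in \[0,1).
#' @param wt_anom_sd Stationary SD (m) of the anomaly.
#' @param wt_weather_coupling Water-table deepening (m) per 100 mm of July
#'   deficit beyond the mean deficit; dry years lower the water table.
#' @param tile_frac Proportion of cells with tile drainage.
#' @param tile_depth Tile-drain depth (m); tiled cells never report water
#'   tables shallower than this.
#' @param deficit_mean,deficit_sd Mean and SD (mm) of the July water deficit.
#' @param deficit_year_share Share of deficit variance common to all cells in
#'   a year (regional weather).
#' @param vpd_mean,vpd_sd July vapour-pressure deficit mean and between-site
#'   SD (kPa).
#' @param awc_mean,awc_sd Soil available water capacity mean and SD (mm).
#' @param base_yield Mean yield under normal weather (t/ha).
#' @param awc_coef Yield response to soil AWC (t/ha per mm deviation).
#' @param drought_sens Base-yield loss per (100 mm deficit beyond -50)^2
#'   (t/ha); the concave decline once the deficit passes -50 mm.
#' @param vpd_sens Relative modulation of `drought_sens` per kPa of VPD above
#'   `vpd_mean` (hotter, drier air makes a given rainfall deficit costlier).
#' @param sm_mean,sm_sd Top-1 m soil moisture mean and residual SD (mm),
#'   top-down (rainfall/ET) sources only.
#' @param sm_deficit_coef,sm_awc_coef Soil-moisture response to deficit and
#'   AWC (mm per mm).
#' @param sm_coef Yield response to root-zone soil moisture (t/ha per mm).
#'   Overridden when `capillary_boost_median` is supplied (see Details).
#' @param capillary_boost_median Calibration target: median relative increase
#'   of soil moisture due to capillary rise over cells within capillary
#'   reach (fraction; default 0.308). Set `NULL` to use `sm_coef` directly.
#' @param capillary_reach Depth (m) within which the water table boosts
#'   root-zone soil moisture; defaults to `gw_effect$d_high` (fringe reach of
#'   ~1 m above a ~1.5 m root zone).
#' @param noise_sd Residual yield noise SD (t/ha).
#' @param month_offsets Mean offsets (m) of May/June/August water tables from
#'   July.
#' @param month_noise_sd Month-specific anomaly SD (m).
#' @param effect_month Month whose depth drives the injected effect
#'   (`"may"`, `"jun"`, `"jul"`, `"aug"`); `"jul"` by default.
#' @param gw_effect A [gw_effect_params()] object.
#' @param gw_effect_form `"bump"` (default) or `"linear"`; the linear variant
#'   (`lin_slope` t/ha per m, centred on the mid depth range) exists for the
#'   closed-form regression-dilution check.
#' @param lin_slope Slope of the linear effect variant (t/ha per m).
#' @param price Price series ($/t): a scalar or one value per year.
#' @param area_per_cell Harvested maize area per cell (ha).
#' @param grain `"grid"` or `"pixel"`.
#' @param pixels_per_cell Locations per cell at pixel grain.
#' @param pixel_depth_sd SD (m) of the persistent local depth offset of a
#'   pixel from its cell mean.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cells = 500, n_years = 20, seed = 1,
                       wt_mean_range = c(0.3, 6.0), wt_ar1 = 0.45,
                       wt_anom_sd = 0.25, wt_weather_coupling = 0.6,
                       tile_frac = 0.25, tile_depth = 1.0,
                       deficit_mean = -60, deficit_sd = 70,
                       deficit_year_share = 0.6,
                       vpd_mean = 1.1, vpd_sd = 0.3,
                       awc_mean = 150, awc_sd = 30,
                       base_yield = 11, awc_coef = 0.003,
                       drought_sens = 0.9, vpd_sens = 1.2,
                       sm_mean = 110, sm_sd = 12,
                       sm_deficit_coef = 0.35, sm_awc_coef = 0.25,
                       sm_coef = 0.006, capillary_boost_median = 0.308,
                       capillary_reach = NULL,
                       noise_sd = 0.7,
                       month_offsets = c(may = -0.35, jun = -0.15, aug = 0.15),
                       month_noise_sd = 0.35,
                       effect_month = "jul",
                       gw_effect = gw_effect_params(),
                       gw_effect_form = c("bump", "linear"), lin_slope = 0.15,
                       price = 170, area_per_cell = 5000,
                       grain = c("grid", "pixel"),
                       pixels_per_cell = 8, pixel_depth_sd = 0.35) {
  if (n_cells < 1 || n_years < 1) {
    stop("sim_config(): n_cells and n_years must be positive", call. = FALSE)
  }
  if (wt_ar1 < 0 || wt_ar1 >= 1) stop("sim_config(): wt_ar1 must be in [0, 1)", call. = FALSE)
  if (tile_frac < 0 || tile_frac > 1) stop("sim_config(): tile_frac in [0, 1]", call. = FALSE)
  stopifnot(inherits(gw_effect, "gw_effect_params"))
  grain <- match.arg(grain)
  gw_effect_form <- match.arg(gw_effect_form)
  effect_month <- match.arg(effect_month, c("may", "jun", "jul", "aug"))
  if (!length(price) %in% c(1L, n_years) || any(price < 0)) {
    stop("sim_config(): price must be a non-negative scalar or one value per year",
         call. = FALSE)
  }
  if (is.null(capillary_reach)) capillary_reach <- gw_effect$d_high
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Simulate the synthetic world
#'
#' Generates the grid-cell-by-year (or pixel-by-year) table described by a
#' [sim_config()]. Water tables follow site mean + AR(1) anomaly + weather
#' coupling (deeper in dry years), truncated at 0.05 m and at `tile_depth`
#' for tiled cells. Yield = base yield (concave in the July water deficit,
#' modulated by VPD and soil AWC) + soil-moisture response + injected
#' groundwater effect + Gaussian noise. The returned table carries the true
#' per-record effect (`true_effect` column) and the depth that generated it
#' (`depth_true`) for oracle use, and records the weather class assigned
#' *after* generation from the realised deficit.
#'
#' The capillary channel: a share `1 - direct_share` of the subsidy operates
#' through root-zone soil moisture. `sm_enhanced` adds the capillary
#' increment `c_max * max(0, 1 - depth/capillary_reach)` to `sm_standard`,
#' with `c_max` scaled so that the soil-moisture yield coefficient times the
#' increment at `d_opt` equals the indirect share of `s_max`. A surrogate
#' conditioned on `sm_standard` therefore attributes the whole effect to
#' depth, while one conditioned on `sm_enhanced` attributes only the direct
#' share — the contrast the mechanism analysis exploits.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A tibble with one row per record; attributes `config`, `c_max`,
#'   `sm_coef_effective`.
#' @export
simulate_world <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (!is.null(seed)) cfg$seed <- seed
  withr::local_seed(cfg$seed)
  p <- cfg$gw_effect
  nc <- cfg$n_cells; ny <- cfg$n_years

  # --- cells ---------------------------------------------------------------
  mu <- runif(nc, cfg$wt_mean_range[1], cfg$wt_mean_range[2])
  tiled <- runif(nc) < cfg$tile_frac
  awc <- rnorm(nc, cfg$awc_mean, cfg$awc_sd)
  drainage <- sample.int(5L, nc, replace = TRUE)
  vpd_cell <- rnorm(nc, cfg$vpd_mean, cfg$vpd_sd)

  # --- weather -------------------------------------------------------------
  yr_sd <- cfg$deficit_sd * sqrt(cfg$deficit_year_share)
  cell_sd <- cfg$deficit_sd * sqrt(1 - cfg$deficit_year_share)
  yr_eff <- rnorm(ny, 0, yr_sd)
  deficit <- matrix(cfg$deficit_mean + rep(yr_eff, each = nc) +
                      rnorm(nc * ny, 0, cell_sd), nc, ny)
  vpd <- matrix(rep(vpd_cell, ny), nc, ny) -
    0.15 * (deficit - cfg$deficit_mean) / cfg$deficit_sd +
    matrix(rnorm(nc * ny, 0, 0.08), nc, ny)

  # --- water tables: AR(1) anomaly + weather coupling ----------------------
  innov_sd <- cfg$wt_anom_sd * sqrt(1 - cfg$wt_ar1^2)
  anom <- matrix(0, nc, ny)
  anom[, 1] <- rnorm(nc, 0, cfg$wt_anom_sd)
  if (ny > 1) for (t in 2:ny) {
    anom[, t] <- cfg$wt_ar1 * anom[, t - 1] + rnorm(nc, 0, innov_sd)
  }
  coupling <- cfg$wt_weather_coupling * (cfg$deficit_mean - deficit) / 100
  clamp <- function(d) {
    d <- pmax(d, 0.05)
    d[rep(tiled, ny)] <- pmax(d[rep(tiled, ny)], cfg$tile_depth)
    d
  }
  jul <- clamp(mu + anom + coupling)
  # the seasonal hydrograph: May sits near the post-recharge high and barely
  # feels the July deficit; the decline steepens through summer, August
  # continuing past July. Month-specific anomalies keep the columns from
  # being July plus a constant.
  mo <- function(off, anom_share, coup_share) {
    clamp(mu + anom_share * anom + off + coup_share * coupling +
            matrix(rnorm(nc * ny, 0, cfg$month_noise_sd), nc, ny))
  }
  may <- mo(cfg$month_offsets[["may"]], 0.5, 0.25)
  jun <- mo(cfg$month_offsets[["jun"]], 0.8, 0.65)
  aug <- mo(cfg$month_offsets[["aug"]], 1.0, 1.2)
  ann <- (may + jun + jul + aug) / 4

  # wider covariate panel emulating the study's selected variable set:
  # correlated weather, soil and topography columns, some with small real
  # yield effects, so the surrogate's six-variables-per-split sampling faces
  # a realistic candidate pool rather than depth at almost every split
  nrec <- nc * ny
  dat <- tibble::tibble(
    cell_id = rep(seq_len(nc), ny),
    year = rep(seq_len(ny), each = nc),
    wt_depth_may = as.vector(may), wt_depth_jun = as.vector(jun),
    wt_depth_jul = as.vector(jul), wt_depth_aug = as.vector(aug),
    wt_depth_annual = as.vector(ann),
    deficit_july = as.vector(deficit), vpd = as.vector(vpd),
    soil_awc = rep(awc, ny), drainage_class = rep(drainage, ny),
    tiled = rep(tiled, ny),
    price = rep(rep_len(cfg$price, ny), each = nc)
  )
  dat$deficit_jun <- 25 + 0.55 * dat$deficit_july + rnorm(nrec, 0, 40)
  dat$precip_may <- pmax(0, 95 + rnorm(nrec, 0, 25))
  dat$vpd_jun <- pmax(0.1, 0.85 * dat$vpd + rnorm(nrec, 0, 0.12))
  dat$gdd <- 1450 + 120 * (dat$vpd - cfg$vpd_mean) + rnorm(nrec, 0, 70)
  dat$planting_doy <- round(rnorm(nrec, 130, 7))
  dat$sand_pct <- pmin(95, pmax(2, rep(55 - 0.15 * (awc - cfg$awc_mean) +
                                         rnorm(nc, 0, 9), ny)))
  dat$clay_pct <- pmin(60, pmax(2, rep(24 + 0.08 * (awc - cfg$awc_mean) +
                                         rnorm(nc, 0, 6), ny)))
  dat$om_pct <- pmax(0.4, rep(3 + 0.01 * (awc - cfg$awc_mean) +
                                rnorm(nc, 0, 0.7), ny))
  dat$ksat <- rep(exp(2.2 + 0.25 * (drainage - 3) + rnorm(nc, 0, 0.35)), ny)
  dat$slope_pct <- rep(abs(rnorm(nc, 1.5, 1.2)), ny)
  dat$elevation_m <- rep(240 + rnorm(nc, 0, 45), ny)
  dat$awc_subsoil <- rep(0.6 * awc + rnorm(nc, 0, 18), ny)
  dat$location_id <- dat$cell_id

  # --- pixel grain: expand with persistent local offsets -------------------
  if (cfg$grain == "pixel") {
    ppc <- cfg$pixels_per_cell
    off_depth <- rnorm(nc * ppc, 0, cfg$pixel_depth_sd)
    off_yield <- rnorm(nc * ppc, 0, 0.3)
    idx <- rep(seq_len(nrow(dat)), each = ppc)
    dat <- dat[idx, ]
    key <- (dat$cell_id - 1) * ppc + rep(seq_len(ppc), length.out = nrow(dat))
    dat$location_id <- key
    dat$pixel_depth_offset <- off_depth[key]
    dat$pixel_yield_offset <- off_yield[key]
  } else {
    dat$pixel_depth_offset <- 0
    dat$pixel_yield_offset <- 0
  }

  # --- true effect ---------------------------------------------------------
  dmonth <- dat[[paste0("wt_depth_", cfg$effect_month)]]
  dat$depth_true <- pmax(0.05, dmonth + dat$pixel_depth_offset)
  if (cfg$gw_effect_form == "bump") {
    dat$true_effect <- true_effect(dat$depth_true, dat$deficit_july, p)
  } else {
    dat$true_effect <- cfg$lin_slope * (dat$depth_true - mean(cfg$wt_mean_range))
  }

  # --- soil moisture and the capillary channel -----------------------------
  dat$sm_standard <- pmax(20, cfg$sm_mean +
    cfg$sm_awc_coef * (dat$soil_awc - cfg$awc_mean) +
    cfg$sm_deficit_coef * (dat$deficit_july - cfg$deficit_mean) +
    rnorm(nrow(dat), 0, cfg$sm_sd))
  reach <- cfg$capillary_reach
  ramp <- pmax(0, 1 - dat$depth_true / reach)
  ramp_opt <- max(0, 1 - p$d_opt / reach)
  sm_coef_eff <- cfg$sm_coef
  c_max <- 0
  if (p$direct_share < 1 && p$s_max > 0 && ramp_opt > 0) {
    if (!is.null(cfg$capillary_boost_median) && any(ramp > 0)) {
      c_max <- cfg$capillary_boost_median /
        median(ramp[ramp > 0] / dat$sm_standard[ramp > 0])
      sm_coef_eff <- (1 - p$direct_share) * p$s_max / (c_max * ramp_opt)
    } else {
      c_max <- (1 - p$direct_share) * p$s_max / (sm_coef_eff * ramp_opt)
    }
  }
  dat$sm_enhanced <- dat$sm_standard + c_max * ramp

  # --- yield ---------------------------------------------------------------
  sens <- pmax(0.1, cfg$drought_sens * (1 + cfg$vpd_sens * (dat$vpd - cfg$vpd_mean)))
  base <- cfg$base_yield + cfg$awc_coef * (dat$soil_awc - cfg$awc_mean) -
    sens * (pmax(0, -50 - dat$deficit_july) / 100)^2 + dat$pixel_yield_offset +
    0.002 * (dat$precip_may - 95) + 0.0012 * (dat$gdd - 1450) +
    0.06 * (dat$om_pct - 3) - 0.004 * (dat$planting_doy - 130)
  dat$yield <- pmax(0.1, base + sm_coef_eff * (dat$sm_standard - cfg$sm_mean) +
                      dat$true_effect + rnorm(nrow(dat), 0, cfg$noise_sd))
  area <- cfg$area_per_cell / if (cfg$grain == "pixel") cfg$pixels_per_cell else 1
  dat$production <- dat$yield * area
  dat$weather_class <- classify_weather(dat$deficit_july)

  dat <- dat[order(dat$year, dat$cell_id, dat$location_id), ]
  attr(dat, "config") <- cfg
  attr(dat, "c_max") <- c_max
  attr(dat, "sm_coef_effective") <- sm_coef_eff
  dat
}

#' Default surrogate predictor panel of the synthetic world
#'
#' The default covariate panel a yield surrogate is fitted on: July
#' depth-to-water, one soil-moisture variant, and the weather and soil
#' covariates that carry real yield signal (July and June water deficits,
#' July and June VPD, May precipitation, soil AWC, drainage class, tile
#' status). Ten columns with six variables tried per split keeps depth
#' competing against other candidates at a split without diluting its
#' signal across so many columns that the effect curve flattens. The
#' generator emits a wider panel (growing degree days, texture fractions,
#' organic matter, conductivity, topography, planting day) for
#' larger-panel experiments via [extended_predictors()].
#'
#' @param sm Which soil-moisture variant to include, `"sm_standard"`
#'   (default; total groundwater effect attributed to depth) or
#'   `"sm_enhanced"` (capillary channel absorbed by the covariate).
#' @return Character vector of column names.
#' @export
world_predictors <- function(sm = c("sm_standard", "sm_enhanced")) {
  sm <- match.arg(sm)
  c("wt_depth_jul", "deficit_july", "vpd", "soil_awc", "drainage_class",
    "tiled", sm, "deficit_jun", "precip_may", "vpd_jun")
}

#' Extended predictor panel of the synthetic world
#'
#' The full emulated covariate panel: [world_predictors()] plus growing
#' degree days, sand/clay/organic-matter fractions, saturated conductivity,
#' slope, elevation, planting day and subsoil AWC (19 columns).
#'
#' @inheritParams world_predictors
#' @return Character vector of column names.
#' @export
extended_predictors <- function(sm = c("sm_standard", "sm_enhanced")) {
  c(world_predictors(sm), "gdd", "sand_pct", "clay_pct", "om_pct", "ksat",
    "slope_pct", "elevation_m", "planting_doy", "awc_subsoil")
}

#' Write a simulated world to a run directory
#'
#' Writes `records.csv` (observable columns), `truth.csv` (per-record true
#' effect and true depth) and `config.json` (resolved configuration,
#' including the injected effect parameters and calibrated capillary scale).
#'
#' @param world A table from [simulate_world()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  obs <- world[, setdiff(names(world), c("true_effect", "depth_true",
                                         "pixel_depth_offset", "pixel_yield_offset"))]
  readr::write_csv(obs, file.path(dir, "records.csv"))
  readr::write_csv(world[, c("cell_id", "location_id", "year", "depth_true",
                             "true_effect")],
                   file.path(dir, "truth.csv"))
  cfg <- attr(world, "config")
  cfg$gw_effect <- unclass(cfg$gw_effect)
  jsonlite::write_json(
    list(config = unclass(cfg), c_max = attr(world, "c_max"),
         sm_coef_effective = attr(world, "sm_coef_effective")),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
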