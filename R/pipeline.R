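#' Load a simulation configuration from JSON
#'
#' Reads a JSON file of [sim_config()] arguments. The keys `n_cells`,
#' `n_years` and `seed` are required; any key that is not a `sim_config`
#' argument is a validation error naming the key. A `gw_effect` sub-object is
#' passed to [gw_effect_params()].
#'
#' @param path JSON file path.
#' @return A `sim_config`.
#' @export
load_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_sim_config(raw)
}

as_sim_config <- function(x) {
  if (inherits(x, "sim_config")) return(x)
  stopifnot(is.list(x))
  required <- c("n_cells", "n_years", "seed")
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    stop("config validation: missing required key(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(x), names(formals(sim_config)))
  if (length(unknown)) {
    stop("config validation: unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(x$gw_effect) && !inherits(x$gw_effect, "gw_effect_params")) {
    x$gw_effect <- do.call(gw_effect_params, as.list(x$gw_effect))
  }
  do.call(sim_config, x)
}

#' Run the full analysis pipeline into a run directory
#'
#' Executes simulate -> evaluate -> fit -> ale -> zones -> stratify ->
#' mechanism -> stability -> prevalence -> monetary (optionally attenuate)
#' on a synthetic world and writes every artifact, plus a manifest recording
#' the resolved configuration, every defaulted analysis parameter (bin
#' count, slope tolerance, boundary conventions, bootstrap settings) and the
#' MD5 hash of each output, so a run is fully auditable and byte-reproducible
#' under the same config and seed. No timestamps are written.
#'
#' @param config A [sim_config()], or a named list of its arguments
#'   (validated; unknown or missing required keys raise an error naming
#'   them).
#' @param out_dir Run directory (created).
#' @param seed Master seed; per-stage child seeds derive from it. Defaults
#'   to `config$seed`.
#' @param k_bins ALE bins.
#' @param stages Character subset of stages to run, in fixed order.
#' @param attenuation_r,attenuation_reps Attenuation stage settings.
#' @param pixels_per_cell Pixel-grain width of the stability world.
#' @param ... Passed to [delineate()].
#' @return The manifest list, invisibly; a stage failure aborts with the
#'   stage name, earlier outputs retained.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, seed = NULL,
                         k_bins = 40,
                         stages = c("simulate", "evaluate", "ale", "zones",
                                    "stratify", "mechanism", "stability",
                                    "prevalence", "attenuate"),
                         attenuation_r = 0.6, attenuation_reps = 2,
                         pixels_per_cell = 4, ...) {
  config <- as_sim_config(config)
  if (is.null(seed)) seed <- config$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- match.arg(stages, several.ok = TRUE)
  written <- character(0)
  note <- function(...) written <<- c(written, file.path(out_dir, c(...)))
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  world <- stage("simulate", {
    w <- simulate_world(config, seed = seed)
    write_world(w, out_dir)
    note("records.csv", "truth.csv", "config.json")
    w
  })

  spec <- surrogate_spec(world_predictors(), seed = child_seed(seed, 1))
  fit <- stage("fit", {
    f <- fit_surrogate(world, spec)
    jsonlite::write_json(
      list(hyperparameters = unclass(spec), oob_r2 = f$oob_r2,
           oob_mse = f$oob_mse, n = nrow(world)),
      file.path(out_dir, "model_manifest.json"), auto_unbox = TRUE, digits = NA)
    note("model_manifest.json")
    f
  })

  if ("evaluate" %in% stages) stage("evaluate", {
    agr <- agreement(world$yield, fit$oob_predictions, world$weather_class)
    readr::write_csv(agr, file.path(out_dir, "agreement_by_class.csv"))
    note("agreement_by_class.csv")
  })

  curve <- NULL; zones <- NULL
  if (any(c("ale", "zones", "stratify", "mechanism", "prevalence",
            "attenuate") %in% stages)) {
    curve <- stage("ale", {
      cv <- compute_ale(fit$predict, world, "wt_depth_jul", k_bins = k_bins)
      write_ale_curve(cv, file.path(out_dir, "ale_curve.csv"))
      note("ale_curve.csv")
      cv
    })
    zones <- stage("zones", {
      z <- delineate(curve, mean_yield = mean(world$yield), ...)
      write_zone_report(z, file.path(out_dir, "zone_report.json"))
      note("zone_report.json")
      z
    })
  }

  if ("stratify" %in% stages) stage("stratify", {
    st <- stratified_effects(fit, world, k_bins = k_bins, ...)
    jsonlite::write_json(
      list(max_subsidy = as.list(st$max_subsidy),
           ratio_very_dry = st$ratio_very_dry),
      file.path(out_dir, "stratified.json"), auto_unbox = TRUE, digits = NA,
      na = "null")
    note("stratified.json")
  })

  # a subsidy too weak to delineate is an expected outcome at demo scale,
  # not a pipeline defect: the dependent experiments record a skip instead
  # of aborting the run
  skip_or <- function(expr) {
    tryCatch(list(ok = TRUE, value = force(expr)), error = function(e) {
      if (grepl("no detect|no subsidy", conditionMessage(e))) {
        list(ok = FALSE, reason = conditionMessage(e))
      } else stop(e)
    })
  }

  if ("mechanism" %in% stages) stage("mechanism", {
    res <- skip_or(suppressMessages(
      mechanism_split(world, k_bins = k_bins, seed = child_seed(seed, 2), ...)))
    boost <- capillary_boost_summary(world)
    body <- if (res$ok) {
      ms <- res$value
      list(direct_share = ms$direct_share, indirect_share = ms$indirect_share,
           effect_standard_sm = ms$effect_standard_sm,
           effect_enhanced_sm = ms$effect_enhanced_sm, d_opt = ms$d_opt,
           capillary_boost = boost)
    } else {
      warning("mechanism stage skipped: ", res$reason, call. = FALSE)
      list(skipped = res$reason, capillary_boost = boost)
    }
    jsonlite::write_json(body, file.path(out_dir, "mechanism.json"),
                         auto_unbox = TRUE, digits = NA)
    note("mechanism.json")
  })

  if ("stability" %in% stages) stage("stability", {
    cfg_px <- config
    cfg_px$grain <- "pixel"
    cfg_px$pixels_per_cell <- pixels_per_cell
    px <- simulate_world(cfg_px, seed = child_seed(seed, 3))
    st <- stability_analysis(px, seed = child_seed(seed, 4))
    readr::write_csv(st$locations[, c("location_id", "cv", "mean_depth",
                                      "vpd_mean", "vpd_tercile")],
                     file.path(out_dir, "stability_locations.csv"))
    write_ale_curve(st$curve_all, file.path(out_dir, "stability_curve.csv"))
    note("stability_locations.csv", "stability_curve.csv")
  })

  if ("prevalence" %in% stages) stage("prevalence", {
    flagged <- if (!is.null(zones) && isTRUE(zones$detected)) {
      flag_conditions(world, zones = zones)
    } else {
      flag_conditions(world, subsidy_low = config$gw_effect$d_low,
                      subsidy_high = config$gw_effect$d_high)
    }
    tl <- tally_prevalence(flagged)
    readr::write_csv(tl$per_cell, file.path(out_dir, "prevalence_per_cell.csv"))
    readr::write_csv(tl$annual_extent, file.path(out_dir, "annual_extent.csv"))
    mon <- monetary_impact(flagged)
    readr::write_csv(mon$annual, file.path(out_dir, "monetary_annual.csv"))
    jsonlite::write_json(
      list(regional = as.list(tl$regional),
           thresholds = attr(flagged, "thresholds"),
           total_subsidy_value = mon$total_subsidy_value,
           total_penalty_cost = mon$total_penalty_cost,
           effect_pcts = as.list(mon$effect_pcts)),
      file.path(out_dir, "prevalence.json"), auto_unbox = TRUE, digits = NA)
    note("prevalence_per_cell.csv", "annual_extent.csv",
         "monetary_annual.csv", "prevalence.json")
  })

  if ("attenuate" %in% stages) stage("attenuate", {
    res <- skip_or(run_attenuation_experiment(world, r_grid = attenuation_r,
                                              n_rep = attenuation_reps,
                                              k_bins = k_bins,
                                              seed = child_seed(seed, 5), ...))
    out <- if (res$ok) {
      res$value$replicates
    } else {
      warning("attenuate stage skipped: ", res$reason, call. = FALSE)
      tibble::tibble(r = numeric(0), rep = integer(0),
                     achieved_r = numeric(0), truncation_rate = numeric(0),
                     value = numeric(0), shrinkage = numeric(0))
    }
    readr::write_csv(out, file.path(out_dir, "attenuation.csv"))
    note("attenuation.csv")
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("gwyield")),
    seed = seed,
    stages = stages,
    analysis_parameters = list(
      k_bins = k_bins,
      surrogate = unclass(spec),
      delineation_defaults = formals(delineate)[c("slope_tol",
                                                  "min_plateau_width",
                                                  "min_effect", "smooth_bw")],
      weather_boundaries = "wet > 0; normal [-50, 0]; dry [-150, -50); very_dry < -150 mm",
      zone_membership = "closed interval [subsidy_low, subsidy_high]",
      bootstrap_default_resamples = 500,
      bootstrap_unit = "cell (cluster bootstrap)"
    ),
    files = lapply(stats::setNames(nm = basename(written)), function(f) {
      unname(tools::md5sum(file.path(out_dir, f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
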