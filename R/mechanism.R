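#' Decompose the subsidy into direct and capillary channels
#'
#' Runs the depth-response analysis twice on the same data and seed, once
#' with the standard (top-down only) soil-moisture covariate and once with
#' the enhanced (top-down + capillary) variant. Under the standard covariate
#' the whole groundwater effect is attributed to depth; under the enhanced
#' covariate the capillary channel is absorbed by the soil-moisture column
#' and only the direct root-uptake share remains on depth. The indirect share
#' is `1 - effect_B(d_opt) / effect_A(d_opt)`, evaluated at run A's optimum
#' depth with both effects measured against run A's free-drainage window;
#' shares are clipped to \[0, 1\] (clipping is messaged) and sum to 1.
#'
#' @param data A world carrying both `sm_standard` and `sm_enhanced`.
#' @param feature Depth column.
#' @param k_bins ALE bins.
#' @param seed Integer seed shared by both fits.
#' @param ... Passed to [delineate()] for run A.
#' @return List with `direct_share`, `indirect_share`, `effect_standard_sm`,
#'   `effect_enhanced_sm` (t/ha at `d_opt`), `d_opt`, `curve_standard`,
#'   `curve_enhanced`, `report_standard`.
#' @export
mechanism_split <- function(data, feature = "wt_depth_jul", k_bins = 40,
                            seed = 1, ...) {
  if (!all(c("sm_standard", "sm_enhanced") %in% names(data))) {
    stop("mechanism_split(): data must carry sm_standard and sm_enhanced",
         call. = FALSE)
  }
  spec_a <- surrogate_spec(world_predictors("sm_standard"), seed = seed)
  spec_b <- surrogate_spec(world_predictors("sm_enhanced"), seed = seed)
  fit_a <- fit_surrogate(data, spec_a)
  fit_b <- fit_surrogate(data, spec_b)
  curve_a <- compute_ale(fit_a$predict, data, feature, k_bins = k_bins)
  report_a <- delineate(curve_a, mean_yield = mean(data$yield), ...)
  if (!isTRUE(report_a$detected) || report_a$max_subsidy <= 0) {
    stop("mechanism_split(): no detectable subsidy under the standard ",
         "soil-moisture covariate; the split is undefined", call. = FALSE)
  }
  curve_b <- compute_ale(fit_b$predict, data, feature, edges = curve_a$edges)
  base_range <- c(report_a$d_free, max(curve_a$edges))
  baseline_b <- measure_subsidy(curve_b, base_range)$baseline
  effect_a <- report_a$max_subsidy
  effect_b <- ale_at(curve_b, report_a$d_opt) - baseline_b
  indirect <- 1 - effect_b / effect_a
  if (indirect < 0 || indirect > 1) {
    message("mechanism_split(): raw indirect share ",
            format(indirect, digits = 3), " clipped to [0, 1]")
    indirect <- min(1, max(0, indirect))
  }
  list(direct_share = 1 - indirect, indirect_share = indirect,
       effect_standard_sm = effect_a, effect_enhanced_sm = effect_b,
       d_opt = report_a$d_opt,
       curve_standard = curve_a, curve_enhanced = curve_b,
       report_standard = report_a)
}

#' Capillary soil-moisture boost summary
#'
#' Per-record relative increase of root-zone soil moisture due to capillary
#' rise, `(sm_enhanced - sm_standard) / sm_standard * 100`, summarised by its
#' median and interquartile range. By default the summary is taken over
#' records within capillary reach (positive increment) — the cells the water
#' table can actually influence; records with zero standard soil moisture
#' are excluded with a message.
#'
#' @param data A world carrying both soil-moisture columns.
#' @param within_reach_only Summarise only records with a positive increment
#'   (default `TRUE`).
#' @return List with `median`, `iqr` (named c(q25, q75)), `n`, `n_excluded`.
#' @export
capillary_boost_summary <- function(data, within_reach_only = TRUE) {
  if (!all(c("sm_standard", "sm_enhanced") %in% names(data))) {
    stop("capillary_boost_summary(): data must carry sm_standard and sm_enhanced",
         call. = FALSE)
  }
  ok <- data$sm_standard > 0
  n_excl <- sum(!ok)
  if (n_excl > 0) message("capillary_boost_summary(): ", n_excl,
                          " records with sm_standard = 0 excluded")
  boost <- (data$sm_enhanced[ok] - data$sm_standard[ok]) / data$sm_standard[ok] * 100
  if (within_reach_only && any(boost > 0)) boost <- boost[boost > 0]
  list(median = median(boost),
       iqr = setNames(quantile(boost, c(0.25, 0.75), names = FALSE),
                      c("q25", "q75")),
       n = length(boost), n_excluded = n_excl)
}
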