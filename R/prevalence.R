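#' Flag penalty, access and subsidy conditions per record
#'
#' Appends boolean condition columns to a cell-year (or pixel-year) table:
#' `penalty` (July depth shallower than the penalty threshold), `access`
#' (depth within the closed subsidy zone \[subsidy_low, subsidy_high\]),
#' `dry` (deficit below -50 mm), `very_dry` (below -150 mm), `subsidy`
#' (access AND dry: groundwater only subsidises yield when it alleviates a
#' yield-limiting deficit) and `strong_subsidy` (access AND very dry).
#' Thresholds come from a delineated [zone_report] or are supplied
#' explicitly; they are recorded in the `thresholds` attribute. Rows with
#' missing depth or deficit are rejected with a message.
#'
#' @param data Table with `wt_depth_jul` and `deficit_july`.
#' @param zones Optional `zone_report` with a detected zone.
#' @param subsidy_low,subsidy_high Zone bounds (m), required when `zones` is
#'   absent; `subsidy_low` doubles as the penalty threshold.
#' @param dry_threshold,very_dry_threshold Deficit thresholds (mm).
#' @return The flagged tibble with attribute `thresholds`.
#' @export
flag_conditions <- function(data, zones = NULL, subsidy_low = NULL,
                            subsidy_high = NULL, dry_threshold = -50,
                            very_dry_threshold = -150) {
  if (!is.null(zones)) {
    stopifnot(inherits(zones, "zone_report"))
    if (!isTRUE(zones$detected)) {
      stop("flag_conditions(): zone report has no detected zone; supply ",
           "subsidy_low/subsidy_high explicitly", call. = FALSE)
    }
    subsidy_low <- zones$subsidy_low
    subsidy_high <- zones$subsidy_high
  }
  if (is.null(subsidy_low) || is.null(subsidy_high)) {
    stop("flag_conditions(): zone bounds required", call. = FALSE)
  }
  ok <- is.finite(data$wt_depth_jul) & is.finite(data$deficit_july)
  if (any(!ok)) {
    message("flag_conditions(): ", sum(!ok),
            " rows with missing depth or deficit rejected")
    data <- data[ok, , drop = FALSE]
  }
  d <- data$wt_depth_jul
  out <- dplyr::mutate(
    data,
    penalty = d < subsidy_low,
    access = d >= subsidy_low & d <= subsidy_high,
    dry = .data$deficit_july < dry_threshold,
    very_dry = .data$deficit_july < very_dry_threshold,
    subsidy = .data$access & .data$dry,
    strong_subsidy = .data$access & .data$very_dry
  )
  attr(out, "thresholds") <- list(
    penalty_threshold = subsidy_low, subsidy_low = subsidy_low,
    subsidy_high = subsidy_high, dry_threshold = dry_threshold,
    very_dry_threshold = very_dry_threshold)
  out
}

#' Tally prevalence of groundwater yield conditions
#'
#' Exact integer counts per cell of penalty, access, dry, very-dry, subsidy
#' and strong-subsidy years, with regional cell-year fractions and the annual
#' geographic extent (fraction of cells with a subsidy each year).
#'
#' @param flagged Output of [flag_conditions()].
#' @return List with `per_cell` (tibble of counts), `regional` (named
#'   fractions of cell-years) and `annual_extent` (tibble: year,
#'   subsidy_extent).
#' @export
tally_prevalence <- function(flagged) {
  flags <- c("penalty", "access", "dry", "very_dry", "subsidy",
             "strong_subsidy")
  if (!all(flags %in% names(flagged))) {
    stop("tally_prevalence(): run flag_conditions() first", call. = FALSE)
  }
  per_cell <- flagged |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(n_years = dplyr::n(),
                     penalty_years = sum(.data$penalty),
                     access_years = sum(.data$access),
                     dry_years = sum(.data$dry),
                     very_dry_years = sum(.data$very_dry),
                     subsidy_years = sum(.data$subsidy),
                     strong_subsidy_years = sum(.data$strong_subsidy),
                     .groups = "drop")
  regional <- vapply(flags, function(f) mean(flagged[[f]]), numeric(1))
  annual <- flagged |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      subsidy_extent = mean(tapply(.data$subsidy, .data$cell_id, any)),
      .groups = "drop")
  list(per_cell = per_cell, regional = regional, annual_extent = annual)
}

#' Monetary impact of groundwater yield interactions
#'
#' Values each flagged cell-year at production x price x applicable effect
#' fraction. A strong-subsidy (very dry) year uses the strong rate *instead
#' of* the ordinary subsidy rate — the stronger applicable rate replaces,
#' never stacks. Penalties are reported as positive costs. Default rates are
#' a 1% penalty, a 3.4% subsidy and a 7.8% strong subsidy of realised
#' production value.
#'
#' @param flagged Output of [flag_conditions()] with `production` and `price`
#'   columns.
#' @param effect_pcts Named fractions: `penalty`, `subsidy`, `strong_subsidy`.
#' @return List with `annual` (tibble: year, subsidy_value, penalty_cost),
#'   `total_subsidy_value`, `total_penalty_cost`, `net_value`, `effect_pcts`.
#' @export
monetary_impact <- function(flagged,
                            effect_pcts = c(penalty = 0.01, subsidy = 0.034,
                                            strong_subsidy = 0.078)) {
  need <- c("production", "price", "penalty", "subsidy", "strong_subsidy")
  if (!all(need %in% names(flagged))) {
    stop("monetary_impact(): need flagged data with production and price",
         call. = FALSE)
  }
  if (any(flagged$production < 0) || any(flagged$price < 0)) {
    stop("monetary_impact(): negative production or price", call. = FALSE)
  }
  stopifnot(all(c("penalty", "subsidy", "strong_subsidy") %in% names(effect_pcts)))
  value <- flagged$production * flagged$price
  sub_rate <- ifelse(flagged$strong_subsidy, effect_pcts[["strong_subsidy"]],
              ifelse(flagged$subsidy, effect_pcts[["subsidy"]], 0))
  pen_rate <- ifelse(flagged$penalty, effect_pcts[["penalty"]], 0)
  df <- tibble::tibble(year = flagged$year,
                       subsidy_value = value * sub_rate,
                       penalty_cost = value * pen_rate)
  annual <- df |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(subsidy_value = sum(.data$subsidy_value),
                     penalty_cost = sum(.data$penalty_cost),
                     .groups = "drop")
  list(annual = annual,
       total_subsidy_value = sum(df$subsidy_value),
       total_penalty_cost = sum(df$penalty_cost),
       net_value = sum(df$subsidy_value) - sum(df$penalty_cost),
       effect_pcts = effect_pcts)
}
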