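# per-bin slope for plateau detection. An estimated ALE curve carries
# accumulated (random-walk) noise, so raw adjacent-edge differences breach
# any sensible flatness tolerance; instead each bin gets the count-weighted
# least-squares slope over a *forward* (deep-side) window of width 2*bw
# metres. The forward window keeps the estimate untouched by the subsidy
# bump's falling limb while scanning from the deep end, so the plateau
# boundary is located without the bias a centred kernel would add. Windows
# holding fewer than 3 edges are widened to the 3 nearest edges. bw = 0
# falls back to raw adjacent-edge slopes (exact for noise-free curves).
local_slopes <- function(curve, bw) {
  e <- curve$edges
  if (bw <= 0) return(diff(curve$effect) / diff(e))
  mids <- (head(e, -1) + tail(e, -1)) / 2
  w0 <- c(curve$counts[1] / 2,
          (head(curve$counts, -1) + tail(curve$counts, -1)) / 2,
          tail(curve$counts, 1) / 2) + 1e-9
  vapply(mids, function(m) {
    inw <- e >= m & e <= m + 2 * bw
    if (sum(inw) < 3) inw <- rank(abs(e - m), ties.method = "first") <= 3
    w <- w0[inw]; x <- e[inw]; y <- curve$effect[inw]
    sw <- sum(w); xb <- sum(w * x) / sw; yb <- sum(w * y) / sw
    sxx <- sum(w * (x - xb)^2)
    if (sxx <= 0) return(0)
    sum(w * (x - xb) * (y - yb)) / sxx
  }, numeric(1))
}

# baseline + max-subsidy against fixed depth windows; shared by the
# stratified and attenuation analyses, where a stratum or noisy curve may not
# have a crisp plateau of its own.
measure_subsidy <- function(curve, baseline_range, search_range = c(0, baseline_range[1])) {
  stopifnot(inherits(curve, "ale_curve"))
  mids <- (head(curve$edges, -1) + tail(curve$edges, -1)) / 2
  mide <- (head(curve$effect, -1) + tail(curve$effect, -1)) / 2
  inb <- mids >= baseline_range[1] & mids <= baseline_range[2]
  if (!any(inb)) return(list(baseline = NA_real_, max_subsidy = NA_real_, d_at_max = NA_real_))
  wts <- curve$counts[inb]
  baseline <- if (sum(wts) > 0) sum(wts * mide[inb]) / sum(wts) else mean(mide[inb])
  ine <- curve$edges > search_range[1] & curve$edges < search_range[2]
  if (!any(ine)) return(list(baseline = baseline, max_subsidy = NA_real_, d_at_max = NA_real_))
  i <- which(ine)[which.max(curve$effect[ine])]
  list(baseline = baseline, max_subsidy = curve$effect[i] - baseline,
       d_at_max = curve$edges[i])
}

#' Delineate subsidy and penalty zones from an ALE curve
#'
#' Implements the zone-reading procedure: (1) scanning from the deep end,
#' the terminal segment whose per-bin slopes (count-weighted local
#' least-squares slopes over a forward window of `2 * smooth_bw`) stay
#' within `coarse_tol`, with its shallow edge refined to the first bin flat
#' at `slope_tol` proper, is the free-drainage plateau; its count-weighted
#' mean effect is the baseline and its shallow end is `d_free`. (2) The optimum `d_opt` is the effect argmax
#' shallower than `d_free`. (3) The shallow subsidy-zone edge `subsidy_low`
#' is the baseline crossing nearest `d_opt` (linear interpolation between
#' edges); it doubles as the waterlogging penalty threshold. (4)
#' `max_subsidy` is the effect at `d_opt` minus the baseline, also expressed
#' as a percent of the mean yield when supplied. (5) The penalty is
#' quantified as baseline minus effect at the count-weighted mean observed
#' depth within the penalty zone.
#'
#' A subsidy is declared only when `max_subsidy` exceeds `min_effect` and —
#' when the curve carries a bootstrap band — the band's lower envelope at
#' `d_opt` clears the baseline. Curves with no qualifying terminal plateau
#' are returned with a `"no free-drainage baseline"` flag (this genuinely
#' happens for noisy curves); curves that never rise above baseline get
#' `"no subsidy detected"`.
#'
#' @param curve An `ale_curve` over depth with at least 10 edges.
#' @param slope_tol Absolute slope tolerance defining "flat" (t/ha per m).
#' @param min_plateau_width Minimum plateau width (m) to accept a baseline.
#' @param min_effect Minimum `max_subsidy` (t/ha) to declare a subsidy.
#' @param mean_yield Mean yield (t/ha) for percent magnitudes.
#' @param smooth_bw Bandwidth (m) of the local-linear slope estimator used
#'   for plateau detection only; 0 falls back to raw adjacent-edge slopes.
#' @param coarse_tol Coarse slope tolerance (t/ha per m) for the robust
#'   terminal-run phase; local drift of an estimated curve stays below it
#'   while the subsidy limb exceeds it.
#' @return An object of class `zone_report`.
#' @export
delineate <- function(curve, slope_tol = 0.02, min_plateau_width = 0.8,
                      min_effect = 0.02, mean_yield = NULL, smooth_bw = 0.5,
                      coarse_tol = 0.1) {
  stopifnot(inherits(curve, "ale_curve"))
  if (length(curve$edges) < 10) {
    stop("delineate(): need a curve with at least 10 edges", call. = FALSE)
  }
  e <- curve$edges; eff <- curve$effect
  K <- length(e) - 1L
  rep0 <- structure(list(
    baseline_effect = NA_real_, d_free = NA_real_, d_opt = NA_real_,
    subsidy_low = NA_real_, subsidy_high = NA_real_,
    penalty_threshold = NA_real_, max_subsidy = NA_real_,
    max_subsidy_pct = NA_real_, max_subsidy_ci = c(NA_real_, NA_real_),
    penalty_at_mean_depth = NA_real_, penalty_at_mean_depth_pct = NA_real_,
    mean_yield = mean_yield %||% NA_real_, detected = FALSE,
    flags = character(0),
    params = list(slope_tol = slope_tol, min_plateau_width = min_plateau_width,
                  min_effect = min_effect, smooth_bw = smooth_bw,
                  coarse_tol = coarse_tol),
    curve = curve), class = "zone_report")

  slopes <- local_slopes(curve, smooth_bw)
  flat <- abs(slopes) <= slope_tol

  # Phase 1 — robust terminal run at a coarse slope tolerance. An estimated
  # curve accumulates random-walk noise, so its deep tail shows diffuse
  # drift whose local slopes can breach slope_tol without the curve leaving
  # the plateau; the genuine subsidy limb, by contrast, is a large localised
  # rise whose slopes exceed coarse_tol. Phase 2 — boundary refinement: the
  # run's shallow edge advances deeper to the first bin that is flat at
  # slope_tol proper, which on a noise-free curve is the exact flatness
  # onset.
  i0 <- K + 1L
  for (j in rev(seq_len(K))) {
    if (abs(slopes[j]) <= coarse_tol) i0 <- j else break
  }
  j0 <- i0
  while (j0 <= K && !flat[j0]) j0 <- j0 + 1L
  if (j0 > K || (e[K + 1L] - e[j0]) < min_plateau_width) {
    rep0$flags <- "no free-drainage baseline"
    return(rep0)
  }
  plateau_bins <- j0:K
  mide <- (eff[plateau_bins] + eff[plateau_bins + 1L]) / 2
  wts <- curve$counts[plateau_bins]
  baseline <- if (sum(wts) > 0) sum(wts * mide) / sum(wts) else mean(mide)
  d_free <- e[j0]

  interior <- which(e < d_free)
  if (!length(interior)) {
    rep0$baseline_effect <- baseline; rep0$d_free <- d_free
    rep0$flags <- "no subsidy detected"
    return(rep0)
  }
  iopt <- interior[which.max(eff[interior])]
  d_opt <- e[iopt]
  max_subsidy <- eff[iopt] - baseline

  detected <- max_subsidy > min_effect
  if (detected && !is.null(curve$band_low)) {
    detected <- curve$band_low[iopt] > baseline
  }
  out <- rep0
  out$baseline_effect <- baseline; out$d_free <- d_free
  out$detected <- detected
  if (!detected) {
    out$flags <- "no subsidy detected"
    return(out)
  }
  out$d_opt <- d_opt
  out$max_subsidy <- max_subsidy
  if (!is.null(curve$band_low)) {
    out$max_subsidy_ci <- c(curve$band_low[iopt] - baseline,
                            curve$band_high[iopt] - baseline)
  }

  # shallow baseline crossing nearest d_opt (conservative zone width)
  subsidy_low <- e[1]
  crossed <- FALSE
  if (iopt > 1) {
    for (i in seq(iopt - 1L, 1L)) {
      if (eff[i] <= baseline) {
        frac <- if (eff[i + 1L] == eff[i]) 0 else
          (baseline - eff[i]) / (eff[i + 1L] - eff[i])
        subsidy_low <- e[i] + frac * (e[i + 1L] - e[i])
        crossed <- TRUE
        break
      }
    }
  }
  if (!crossed) out$flags <- c(out$flags, "zone truncated at shallow end")
  out$subsidy_low <- subsidy_low
  out$subsidy_high <- d_free
  out$penalty_threshold <- subsidy_low

  # penalty at the count-weighted mean depth inside the penalty zone
  mids <- (head(e, -1) + tail(e, -1)) / 2
  pen_bins <- which(mids < subsidy_low & curve$counts > 0)
  if (length(pen_bins)) {
    dbar <- sum(curve$counts[pen_bins] * mids[pen_bins]) / sum(curve$counts[pen_bins])
    out$penalty_at_mean_depth <- baseline - ale_at(curve, dbar)
    attr(out$penalty_at_mean_depth, "depth") <- dbar
  }
  if (!is.null(mean_yield) && is.finite(mean_yield) && mean_yield > 0) {
    out$max_subsidy_pct <- out$max_subsidy / mean_yield * 100
    if (is.finite(out$penalty_at_mean_depth %||% NA_real_)) {
      out$penalty_at_mean_depth_pct <- as.numeric(out$penalty_at_mean_depth) / mean_yield * 100
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.zone_report <- function(x, ...) {
  cat("<zone_report>\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  cat("  baseline:", format(x$baseline_effect, digits = 3),
      "t/ha | free drainage from", format(x$d_free, digits = 3), "m\n")
  if (isTRUE(x$detected)) {
    cat("  subsidy zone:", format(x$subsidy_low, digits = 3), "-",
        format(x$subsidy_high, digits = 3), "m, optimum",
        format(x$d_opt, digits = 3), "m\n")
    cat("  max subsidy:", format(x$max_subsidy, digits = 3), "t/ha",
        if (is.finite(x$max_subsidy_pct))
          paste0("(", format(x$max_subsidy_pct, digits = 2), "% of mean yield)"),
        "\n")
  }
  invisible(x)
}

#' Serialise a zone report as JSON
#' @param report A `zone_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_zone_report <- function(report, path) {
  x <- unclass(report)
  x$curve <- NULL
  x$penalty_at_mean_depth <- as.numeric(x$penalty_at_mean_depth)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' Depth effects stratified by weather class
#'
#' Re-evaluates the fitted surrogate's ALE over depth within strata (July
#' weather classes by default), on the all-sample bin edges so curves are
#' comparable, and each stratum's maximum subsidy is measured against the
#' all-sample free-drainage window.
#'
#' The very-dry : all-sample subsidy ratio — the drought-amplification
#' estimate — is computed from *size-matched refits*: one surrogate fitted
#' on the very-dry rows and one on an equally sized random subsample of all
#' rows, both measured identically. A single pooled model expresses a
#' depth-by-deficit interaction only as far as the ensemble has learned it,
#' which systematically pulls the re-evaluated stratum contrast toward 1;
#' matching the two refits' sample sizes makes their small-sample
#' attenuation comparable so it cancels in the ratio.
#'
#' @param fit A `gw_surrogate` fitted on the full sample.
#' @param data The full table.
#' @param feature Depth column (default `"wt_depth_jul"`).
#' @param by Stratifying column (default `"weather_class"`).
#' @param k_bins ALE bins for the all-sample curve.
#' @param min_n Minimum stratum size; smaller strata are skipped with a
#'   warning.
#' @param ratio_stratum Stratum whose size-matched ratio is computed
#'   (default `"very_dry"`); `NULL` skips the refits.
#' @param seed Integer seed for the size-matched subsample and refits.
#' @param ... Passed to [delineate()] for the all-sample report.
#' @return List with `all` (curve), `report` (all-sample `zone_report`),
#'   `strata` (named list of re-evaluated curves), `max_subsidy` (named
#'   vector incl. `"all"`), and `ratio_very_dry` (size-matched refit ratio).
#' @export
stratified_effects <- function(fit, data, feature = "wt_depth_jul",
                               by = "weather_class", k_bins = 40,
                               min_n = 200, ratio_stratum = "very_dry",
                               seed = 1, ...) {
  stopifnot(inherits(fit, "gw_surrogate"))
  curve <- compute_ale(fit$predict, data, feature, k_bins = k_bins)
  report <- delineate(curve, mean_yield = mean(data[[fit$spec$target]]), ...)
  if (!isTRUE(report$detected)) {
    warning("stratified_effects(): no subsidy detected on the full sample",
            call. = FALSE)
  }
  base_range <- c(report$d_free %||% quantile(data[[feature]], 0.7),
                  max(curve$edges))
  search <- c(0, base_range[1])
  ms_all <- measure_subsidy(curve, base_range, search)
  strata <- list(); ms <- c(all = ms_all$max_subsidy)
  for (lev in levels(factor(data[[by]]))) {
    rows <- data[[by]] == lev
    if (sum(rows) < min_n) {
      warning("stratified_effects(): stratum '", lev, "' below min_n; skipped",
              call. = FALSE)
      next
    }
    cs <- compute_ale(fit$predict, data[rows, , drop = FALSE], feature,
                      edges = curve$edges)
    strata[[lev]] <- cs
    ms[lev] <- measure_subsidy(cs, base_range, search)$max_subsidy
  }

  ratio <- NA_real_
  if (!is.null(ratio_stratum) && ratio_stratum %in% names(strata)) {
    rows <- which(data[[by]] == ratio_stratum)
    refit_ms <- function(d, k) {
      sp <- fit$spec
      sp$seed <- child_seed(seed, k)
      f <- fit_surrogate(d, sp)
      cv <- suppressWarnings(compute_ale(f$predict, d, feature,
                                         edges = curve$edges))
      measure_subsidy(cv, base_range, search)$max_subsidy
    }
    withr::local_seed(child_seed(seed, 99))
    ref_rows <- sample(nrow(data), length(rows))
    ms_stratum <- refit_ms(data[rows, , drop = FALSE], 1L)
    ms_ref <- refit_ms(data[ref_rows, , drop = FALSE], 2L)
    if (is.finite(ms_stratum) && is.finite(ms_ref) && ms_ref > 0) {
      ratio <- ms_stratum / ms_ref
    }
  }
  list(all = curve, report = report, strata = strata,
       max_subsidy = ms, ratio_very_dry = ratio)
}
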