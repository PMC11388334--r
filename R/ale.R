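#' First-order accumulated local effects (ALE)
#'
#' From-scratch first-order ALE estimator. The feature axis is discretised at
#' sample quantiles; within each bin the local effect of the feature is the
#' model prediction at the bin's upper edge minus the prediction at its lower
#' edge, holding every other covariate at its observed value. Per-bin mean
#' local effects are accumulated by cumulative sum and the curve is centred
#' at the count-weighted mean prediction, so effects read as t/ha relative to
#' the population mean. Because local effects condition on the observed
#' covariates within each bin, the estimator remains meaningful under
#' correlated predictors, unlike partial dependence.
#'
#' @param predict_fn Function mapping a data frame of covariates to a numeric
#'   vector of predictions (black-box model).
#' @param data Data frame containing `feature` and every covariate
#'   `predict_fn` needs.
#' @param feature Name of the numeric feature to accumulate over.
#' @param k_bins Number of quantile bins (>= 2). Duplicate quantile edges
#'   (heavy ties) are merged with a warning and counts pooled.
#' @param edges Optional fixed bin edges (overrides `k_bins`); used to align
#'   curves across resamples or strata.
#' @return An object of class `ale_curve`: list with `edges` (K+1 values),
#'   `effect` (K+1 centred effects), `counts` (K per-bin counts), `feature`,
#'   `center` (the subtracted mean).
#' @export
compute_ale <- function(predict_fn, data, feature, k_bins = 40, edges = NULL) {
  stopifnot(is.function(predict_fn), is.data.frame(data))
  if (!feature %in% names(data)) {
    stop("compute_ale(): feature '", feature, "' not in data", call. = FALSE)
  }
  x <- data[[feature]]
  if (!is.numeric(x)) stop("compute_ale(): feature must be numeric", call. = FALSE)
  if (length(unique(x)) < 2) {
    stop("compute_ale(): feature is constant", call. = FALSE)
  }
  if (is.null(edges)) {
    if (k_bins < 2) stop("compute_ale(): k_bins >= 2 required", call. = FALSE)
    if (nrow(data) < k_bins) {
      stop("compute_ale(): need n >= k_bins", call. = FALSE)
    }
    edges <- quantile(x, probs = seq(0, 1, length.out = k_bins + 1),
                      names = FALSE, type = 7)
    dedup <- unique(edges)
    if (length(dedup) < length(edges)) {
      warning("compute_ale(): ", length(edges) - length(dedup),
              " duplicate quantile edges merged", call. = FALSE)
      edges <- dedup
    }
  } else {
    edges <- sort(unique(as.numeric(edges)))
  }
  K <- length(edges) - 1L
  if (K < 1) stop("compute_ale(): need at least one bin", call. = FALSE)

  bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  lo <- data; lo[[feature]] <- edges[bin]
  hi <- data; hi[[feature]] <- edges[bin + 1L]
  delta <- predict_fn(hi) - predict_fn(lo)
  counts <- tabulate(bin, nbins = K)
  sums <- numeric(K)
  agg <- tapply(delta, factor(bin, levels = seq_len(K)), sum)
  sums[!is.na(agg)] <- agg[!is.na(agg)]
  bin_means <- ifelse(counts > 0, sums / pmax(counts, 1L), 0)

  acc <- c(0, cumsum(bin_means))
  center <- sum(counts * (acc[seq_len(K)] + acc[seq_len(K) + 1L]) / 2) / sum(counts)
  new_ale_curve(edges, acc - center, counts, feature, center)
}

new_ale_curve <- function(edges, effect, counts, feature, center,
                          band_low = NULL, band_high = NULL) {
  structure(list(edges = edges, effect = effect, counts = counts,
                 feature = feature, center = center,
                 band_low = band_low, band_high = band_high),
            class = "ale_curve")
}

#' @export
print.ale_curve <- function(x, ...) {
  cat("<ale_curve> feature:", x$feature, "|", length(x$counts), "bins, n =",
      sum(x$counts), "\n")
  cat("  range:", format(min(x$edges), digits = 4), "to",
      format(max(x$edges), digits = 4), "| effect:",
      format(min(x$effect), digits = 3), "to", format(max(x$effect), digits = 3),
      if (!is.null(x$band_low)) "| bootstrap band attached" else "", "\n")
  invisible(x)
}

#' Tidy an ALE curve
#'
#' @param curve An `ale_curve`.
#' @return A tibble with one row per edge: `edge`, `effect`, `count`
#'   (count of the bin below the edge; 0 for the first edge), and band
#'   columns when present.
#' @export
ale_table <- function(curve) {
  stopifnot(inherits(curve, "ale_curve"))
  out <- tibble::tibble(edge = curve$edges, effect = curve$effect,
                        count = c(0L, curve$counts))
  if (!is.null(curve$band_low)) {
    out$band_low <- curve$band_low
    out$band_high <- curve$band_high
  }
  out
}

#' Interpolate an ALE curve at arbitrary feature values
#'
#' Linear interpolation between edges; constant extrapolation beyond the
#' first/last edge.
#'
#' @param curve An `ale_curve`.
#' @param x Feature values.
#' @return Effect values at `x`.
#' @export
ale_at <- function(curve, x) {
  stopifnot(inherits(curve, "ale_curve"))
  approx(curve$edges, curve$effect, xout = x, rule = 2)$y
}

#' Count-weighted slope of an ALE curve
#'
#' Weighted least-squares slope of the edge effects against the edges over a
#' central range of the feature distribution; used to compare a curve against
#' a linear effect (e.g. the regression-dilution closed form).
#'
#' @param curve An `ale_curve`.
#' @param probs Central count-quantile range to use (default 5--95%).
#' @return Slope in effect units per feature unit.
#' @export
ale_slope <- function(curve, probs = c(0.05, 0.95)) {
  stopifnot(inherits(curve, "ale_curve"))
  w <- c(curve$counts[1] / 2,
         (head(curve$counts, -1) + tail(curve$counts, -1)) / 2,
         tail(curve$counts, 1) / 2)
  cum <- cumsum(c(0L, curve$counts)) / sum(curve$counts)
  keep <- cum >= probs[1] & cum <= probs[2]
  if (sum(keep) < 2) keep <- rep(TRUE, length(cum))
  fit <- lm(curve$effect[keep] ~ curve$edges[keep], weights = w[keep] + 1e-9)
  unname(coef(fit)[2])
}

#' Cluster-bootstrap band for an ALE curve
#'
#' Refits the surrogate on resampled data and recomputes the ALE curve on the
#' original curve's bin edges, returning the point curve with a percentile
#' 2.5/97.5% envelope. The resampling unit is the cluster (grid cell by
#' default), not the row, so within-cell dependence is respected.
#'
#' @param predict_factory Function taking a resampled data frame and
#'   returning a prediction function (i.e. a refit of the surrogate).
#' @param data Data frame with the covariates and the cluster column.
#' @param feature Feature to accumulate over.
#' @param k_bins Bins for the point curve.
#' @param n_boot Number of bootstrap resamples (>= 2; 500 is a sensible
#'   production default, tests use fewer).
#' @param seed Integer seed for the resampling.
#' @param cluster Name of the cluster id column (default `"cell_id"`).
#' @return The point `ale_curve` with `band_low`/`band_high` attached and an
#'   attribute `n_boot_used`. Resamples whose refit fails are dropped with a
#'   warning; more than 10% failures is an error.
#' @export
bootstrap_ale <- function(predict_factory, data, feature, k_bins = 40,
                          n_boot = 500, seed = 1, cluster = "cell_id") {
  stopifnot(is.function(predict_factory), n_boot >= 2)
  if (!cluster %in% names(data)) {
    stop("bootstrap_ale(): cluster column '", cluster, "' not in data",
         call. = FALSE)
  }
  point <- compute_ale(predict_factory(data), data, feature, k_bins = k_bins)
  ids <- unique(data[[cluster]])
  rows_by_id <- split(seq_len(nrow(data)), data[[cluster]])
  withr::local_seed(seed)
  mat <- matrix(NA_real_, nrow = length(point$edges), ncol = n_boot)
  failed <- 0L
  for (b in seq_len(n_boot)) {
    take <- sample(ids, length(ids), replace = TRUE)
    rows <- unlist(rows_by_id[as.character(take)], use.names = FALSE)
    dd <- data[rows, , drop = FALSE]
    cb <- tryCatch({
      pf <- predict_factory(dd)
      compute_ale(pf, dd, feature, edges = point$edges)
    }, error = function(e) NULL)
    if (is.null(cb)) failed <- failed + 1L else mat[, b] <- cb$effect
  }
  if (failed > 0) {
    warning("bootstrap_ale(): ", failed, " resample(s) dropped after refit failure",
            call. = FALSE)
    if (failed > 0.1 * n_boot) {
      stop("bootstrap_ale(): more than 10% of resamples failed", call. = FALSE)
    }
  }
  ok <- !is.na(mat[1, ])
  point$band_low <- apply(mat[, ok, drop = FALSE], 1, quantile, probs = 0.025)
  point$band_high <- apply(mat[, ok, drop = FALSE], 1, quantile, probs = 0.975)
  attr(point, "n_boot_used") <- sum(ok)
  point
}

#' Plot an ALE curve
#'
#' Effect curve with the zero line, optional bootstrap ribbon and a rug of
#' the feature distribution (bin edges weighted by counts).
#'
#' @param curve An `ale_curve`.
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
plot_ale <- function(curve, xlab = curve$feature, ylab = "effect (t/ha)") {
  df <- ale_table(curve)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$edge, y = .data$effect))
  if (!is.null(curve$band_low)) {
    gg <- gg + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$band_low, ymax = .data$band_high),
      fill = "grey80")
  }
  gg + ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_rug(sides = "b", alpha = 0.3) +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}

#' Write an ALE curve as CSV
#'
#' @param curve An `ale_curve`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ale_curve <- function(curve, path) {
  readr::write_csv(ale_table(curve), path)
  invisible(path)
}
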