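#' Surrogate model specification
#'
#' Hyperparameters for the bagged regression-tree yield surrogate: 100 trees,
#' six candidate variables per split and a minimum node size of 10 — chosen
#' to resist overfitting while leaving the ensemble flexible enough to trace
#' a sub-half-tonne effect over depth.
#'
#' @param predictors Character vector of predictor column names.
#' @param target Target column name (default `"yield"`).
#' @param n_trees Number of trees (default 100).
#' @param m_try Variables tried per split (default `min(6, length(predictors))`).
#' @param min_node Minimum node size (default 10).
#' @param seed Integer seed; fitting is deterministic given the seed and row
#'   order.
#' @return An object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(predictors, target = "yield", n_trees = 100,
                           m_try = min(6L, length(predictors)), min_node = 10,
                           seed = 1) {
  if (m_try > length(predictors)) {
    stop("surrogate_spec(): m_try must be <= number of predictors", call. = FALSE)
  }
  structure(list(predictors = predictors, target = target,
                 n_trees = as.integer(n_trees), m_try = as.integer(m_try),
                 min_node = as.integer(min_node), seed = as.integer(seed)),
            class = "surrogate_spec")
}

#' Fit the yield surrogate
#'
#' Fits a bagged regression-tree ensemble (via `ranger`) of the target on the
#' specified predictors and evaluates it on out-of-bag samples. Refitting
#' with the same seed and the same row order is bit-reproducible.
#'
#' @param data Data frame with no missing values in predictors or target.
#' @param spec A [surrogate_spec()].
#' @return An object of class `gw_surrogate`: list with the fitted `model`,
#'   the `spec`, a `predict(newdata)` function, and out-of-bag `oob_r2` and
#'   `oob_mse`.
#' @export
fit_surrogate <- function(data, spec) {
  stopifnot(inherits(spec, "surrogate_spec"))
  cols <- c(spec$predictors, spec$target)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("fit_surrogate(): missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyNA(data[cols])) {
    stop("fit_surrogate(): missing values in predictors or target", call. = FALSE)
  }
  if (nrow(data) < 2 * spec$min_node) {
    stop("fit_surrogate(): fewer rows than 2 * min_node", call. = FALSE)
  }
  x <- as.data.frame(data[spec$predictors])
  model <- ranger::ranger(
    x = x, y = data[[spec$target]],
    num.trees = spec$n_trees, mtry = spec$m_try,
    min.node.size = spec$min_node, seed = spec$seed,
    num.threads = 1, verbose = FALSE
  )
  predictors <- spec$predictors
  structure(list(
    model = model, spec = spec,
    predict = function(newdata) {
      predict(model, as.data.frame(newdata[predictors]),
              num.threads = 1)$predictions
    },
    oob_predictions = model$predictions,
    oob_r2 = model$r.squared,
    oob_mse = model$prediction.error
  ), class = "gw_surrogate")
}

#' @export
print.gw_surrogate <- function(x, ...) {
  cat("<gw_surrogate>", x$spec$n_trees, "trees, mtry", x$spec$m_try,
      ", min node", x$spec$min_node, "\n")
  cat("  target:", x$spec$target, "on", length(x$spec$predictors),
      "predictors | OOB R2 =", format(x$oob_r2, digits = 3),
      ", OOB MSE =", format(x$oob_mse, digits = 3), "\n")
  invisible(x)
}

#' Screen the relevant groundwater time step
#'
#' Greedy forward selection over candidate water-table depth columns (May to
#' August plus the annual mean) on out-of-bag mean squared error: starting
#' from the non-depth covariate panel, the candidate whose addition most
#' reduces OOB MSE is added, and selection stops when the best relative
#' improvement falls below `min_rel_gain`. OOB error uses every row without
#' a holdout split, which keeps the candidate ranking stable at moderate
#' sample sizes. Returns the selected columns in selection order — possibly
#' none, when no depth column helps.
#'
#' @param data Data frame (a simulated world or equivalent).
#' @param candidates Candidate depth columns.
#' @param base_predictors Always-included covariates (default: the world
#'   panel minus the depth column).
#' @param target Target column.
#' @param n_trees Trees used for the screening fits (smaller than the
#'   production surrogate; only the ranking matters).
#' @param min_rel_gain Minimum relative OOB-MSE improvement to accept a
#'   candidate.
#' @param seed Integer seed for the fits.
#' @return Character vector of selected columns in order.
#' @export
screen_groundwater_period <- function(
    data,
    candidates = c("wt_depth_may", "wt_depth_jun", "wt_depth_jul",
                   "wt_depth_aug", "wt_depth_annual"),
    base_predictors = setdiff(world_predictors(), "wt_depth_jul"),
    target = "yield", n_trees = 100,
    min_rel_gain = 0.01, seed = 1) {
  # all fits within a selection round share one seed (common random numbers:
  # identical bootstrap resamples), so candidate comparisons are paired and
  # fit-to-fit noise largely cancels
  oob_mse <- function(preds, round) {
    sp <- surrogate_spec(preds, target = target, n_trees = n_trees,
                         m_try = min(6L, length(preds)),
                         seed = child_seed(seed, round))
    fit_surrogate(data, sp)$oob_mse
  }
  selected <- character(0)
  remaining <- candidates
  while (length(remaining)) {
    round <- length(selected) + 1L
    current <- oob_mse(c(base_predictors, selected), round)
    mses <- vapply(seq_along(remaining), function(i) {
      oob_mse(c(base_predictors, selected, remaining[i]), round)
    }, numeric(1))
    best <- which.min(mses)
    gain <- (current - mses[best]) / current
    if (!is.finite(gain) || gain < min_rel_gain) break
    selected <- c(selected, remaining[best])
    remaining <- remaining[-best]
  }
  selected
}
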