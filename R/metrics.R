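#' July water deficit
#'
#' Monthly water deficit defined as precipitation minus potential
#' evapotranspiration (PET). Negative values indicate a deficit. This is a
#' non-standardised analogue of SPEI-type drought indices; no standardisation
#' is applied by design.
#'
#' @param precip Precipitation (mm), finite.
#' @param pet Potential evapotranspiration (mm), finite and non-negative.
#' @return Water deficit in mm (vectorised); negative = deficit.
#' @examples
#' water_deficit(30, 180) # -150
#' @export
water_deficit <- function(precip, pet) {
  if (!all(is.finite(precip)) || !all(is.finite(pet))) {
    stop("water_deficit(): `precip` and `pet` must be finite", call. = FALSE)
  }
  if (any(pet < 0)) stop("water_deficit(): `pet` must be >= 0", call. = FALSE)
  precip - pet
}

#' Weather class boundaries (mm of July water deficit)
#'
#' Breaks at 0, -50 and -150 mm separate wet, normal, dry and very-dry July
#' conditions.
#' @export
weather_breaks <- c(wet = 0, dry = -50, very_dry = -150)

#' Classify July weather from the water deficit
#'
#' Maps a July water deficit (mm) onto the four weather classes:
#' wet (deficit > 0), normal (-50 <= deficit <= 0), dry
#' (-150 <= deficit < -50) and very_dry (deficit < -150). The shared
#' endpoints -50 and -150 belong to the wetter class of each pair (closed
#' upper bound of the dry-side interval); this convention is fixed and
#' documented here because interval notation alone leaves it ambiguous.
#'
#' @param deficit July water deficit in mm (vectorised), finite.
#' @return Factor with levels `wet`, `normal`, `dry`, `very_dry`.
#' @examples
#' classify_weather(c(10, -25, -75, -200))
#' @export
classify_weather <- function(deficit) {
  if (!all(is.finite(deficit))) {
    stop("classify_weather(): `deficit` must be finite", call. = FALSE)
  }
  cls <- ifelse(deficit > 0, "wet",
         ifelse(deficit >= -50, "normal",
         ifelse(deficit >= -150, "dry", "very_dry")))
  factor(cls, levels = c("wet", "normal", "dry", "very_dry"))
}

#' Coefficient of variation (percent)
#'
#' CV = SD / mean * 100, using the sample (n - 1) standard deviation. Used as
#' the interannual yield-stability measure: lower CV means more stable yields.
#'
#' @param values Numeric series (e.g. yields in t/ha), length >= 2, mean > 0.
#' @return CV in percent.
#' @examples
#' coefficient_of_variation(c(8, 10, 12)) # 20
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) {
    stop("coefficient_of_variation(): need at least 2 values", call. = FALSE)
  }
  m <- mean(values)
  if (!is.finite(m) || m <= 0) {
    stop("coefficient_of_variation(): undefined for mean <= 0", call. = FALSE)
  }
  sd(values) / m * 100
}

#' Agreement between observed and predicted series
#'
#' Computes the squared Pearson correlation (R^2) and the root mean square
#' error between paired series, overall and optionally within weather classes.
#' Note the R^2 here is the squared correlation, not 1 - SSE/SST, so it is
#' insensitive to additive bias (a uniformly shifted prediction still scores
#' R^2 = 1 while the RMSE reports the shift).
#'
#' @param observed,predicted Equal-length numeric series, n >= 3.
#' @param class Optional factor/character of the same length (e.g. weather
#'   classes); when supplied, one row per class is appended.
#' @return A tibble with columns `class`, `n`, `r2`, `rmse`. `r2` is `NA`
#'   (with a warning) when either series has zero variance.
#' @export
agreement <- function(observed, predicted, class = NULL) {
  if (length(observed) != length(predicted)) {
    stop("agreement(): series must have equal length", call. = FALSE)
  }
  if (length(observed) < 3) stop("agreement(): need n >= 3", call. = FALSE)
  one <- function(o, p, label) {
    r2 <- NA_real_
    if (sd(o) > 0 && sd(p) > 0) {
      r2 <- cor(o, p)^2
    } else {
      warning("agreement(): zero variance in a series; r2 undefined for '",
              label, "'", call. = FALSE)
    }
    tibble::tibble(class = label, n = length(o),
                   r2 = r2, rmse = sqrt(mean((o - p)^2)))
  }
  out <- one(observed, predicted, "all")
  if (!is.null(class)) {
    class <- as.character(class)
    for (cl in unique(class)) {
      idx <- class == cl
      if (sum(idx) >= 3) out <- dplyr::bind_rows(out, one(observed[idx], predicted[idx], cl))
    }
  }
  out
}
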