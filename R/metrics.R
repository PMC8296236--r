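#' The eight daily temperature metrics
#'
#' Closed enumeration, in the canonical reporting order: daily mean (tmean),
#' daily maximum (tmax), daytime maximum (tmax_day), daily minimum (tmin),
#' nighttime minimum (tmin_night), and the three apparent-temperature
#' variants combining heat and humidity (tmean_app, tmax_app, tmin_app).
#' This ordering is also the deterministic tie-break order in metric
#' selection.
#'
#' @return character vector of length 8.
#' @export
metric_names <- function() {
  c("tmean", "tmax", "tmax_day", "tmin", "tmin_night",
    "tmean_app", "tmax_app", "tmin_app")
}

#' Apparent temperature from air temperature and dew point
#'
#' Combined heat-humidity exposure index. The default is the
#' Kalkstein-Valimont dew-point form
#' \deqn{AT = -2.653 + 0.994\,T + 0.0153\,T_d^2}
#' with both temperatures in degrees Celsius. The alternative Steadman
#' vapour-pressure form \eqn{AT = -1.3 + 0.92\,T + 2.2\,e} (with \eqn{e} the
#' vapour pressure in kPa derived from the dew point) is selectable.
#'
#' Non-finite inputs yield `NA` (missing marker). Dew points far above the
#' air temperature (supersaturation beyond 5 degrees C) are rejected.
#'
#' @param t_air air temperature, degrees C.
#' @param dew_point dew point temperature, degrees C.
#' @param formula `"kalkstein"` (default) or `"steadman"`.
#' @return apparent temperature, degrees C; `NA` where inputs are missing.
#' @export
apparent_temperature <- function(t_air, dew_point,
                                 formula = c("kalkstein", "steadman")) {
  formula <- match.arg(formula)
  stopifnot(length(t_air) == length(dew_point))
  ok <- is.finite(t_air) & is.finite(dew_point)
  if (any(dew_point[ok] > t_air[ok] + 5))
    stop("dew point exceeds air temperature by more than 5 degrees C")
  out <- rep(NA_real_, length(t_air))
  if (formula == "kalkstein") {
    out[ok] <- -2.653 + 0.994 * t_air[ok] + 0.0153 * dew_point[ok]^2
  } else {
    # saturation vapour pressure at the dew point = actual vapour pressure
    e_kpa <- 0.6108 * exp(17.27 * dew_point[ok] / (237.7 + dew_point[ok]))
    out[ok] <- -1.3 + 0.92 * t_air[ok] + 2.2 * e_kpa
  }
  out
}

#' Dew point from relative humidity (Magnus approximation)
#'
#' Inverts the Magnus saturation-vapour-pressure formula with alpha = 17.27,
#' beta = 237.7 degrees C.
#'
#' @param t_air air temperature, degrees C.
#' @param rh relative humidity in percent (0-100].
#' @return dew point, degrees C; `NA` where inputs are missing.
#' @export
dewpoint_from_rh <- function(t_air, rh, alpha = 17.27, beta = 237.7) {
  ok <- is.finite(t_air) & is.finite(rh) & rh > 0
  g <- rep(NA_real_, length(t_air))
  g[ok] <- log(rh[ok] / 100) + alpha * t_air[ok] / (beta + t_air[ok])
  ifelse(ok, beta * g / (alpha - g), NA_real_)
}

#' Derive the eight temperature metrics from raw weather columns
#'
#' The five plain metrics (`tmean`, `tmax`, `tmax_day`, `tmin`,
#' `tmin_night`) pass through bit-exact. The three apparent variants apply
#' [apparent_temperature()] to (tmean, daily-mean dew point), (tmax, dew
#' point at time of maximum), (tmin, dew point at time of minimum). Dew
#' points come from `dewpoint*` columns when present, otherwise from `rh*`
#' columns via [dewpoint_from_rh()]; when a time-resolved humidity input is
#' absent the daily mean is used and the fallback recorded in the
#' `"fallbacks"` attribute. Days with no humidity input get `NA` apparent
#' metrics.
#'
#' @param raw data.frame with columns `tmean`, `tmax`, `tmax_day`, `tmin`,
#'   `tmin_night` and either `dewpoint_mean`/`dewpoint_max_time`/
#'   `dewpoint_min_time` or `rh_mean`/`rh_max_time`/`rh_min_time`.
#' @param formula apparent-temperature form, see [apparent_temperature()].
#' @return data.frame with the eight metric columns in canonical order.
#' @export
derive_metrics <- function(raw, formula = c("kalkstein", "steadman")) {
  formula <- match.arg(formula)
  plain <- c("tmean", "tmax", "tmax_day", "tmin", "tmin_night")
  missing_cols <- setdiff(plain, names(raw))
  if (length(missing_cols))
    stop("raw weather data lacks columns: ", paste(missing_cols, collapse = ", "))
  n <- nrow(raw)
  fallbacks <- character(0)

  dew_for <- function(temp_col, dew_col, rh_col) {
    if (dew_col %in% names(raw)) return(raw[[dew_col]])
    if (rh_col %in% names(raw))
      return(dewpoint_from_rh(raw[[temp_col]], raw[[rh_col]]))
    # fall back to the daily mean dew point
    fallbacks <<- c(fallbacks, temp_col)
    if ("dewpoint_mean" %in% names(raw)) return(raw$dewpoint_mean)
    if ("rh_mean" %in% names(raw))
      return(dewpoint_from_rh(raw$tmean, raw$rh_mean))
    rep(NA_real_, n)
  }

  dew_mean <- if ("dewpoint_mean" %in% names(raw)) raw$dewpoint_mean
              else if ("rh_mean" %in% names(raw)) dewpoint_from_rh(raw$tmean, raw$rh_mean)
              else rep(NA_real_, n)
  dew_max <- dew_for("tmax", "dewpoint_max_time", "rh_max_time")
  dew_min <- dew_for("tmin", "dewpoint_min_time", "rh_min_time")

  out <- data.frame(
    tmean      = raw$tmean,
    tmax       = raw$tmax,
    tmax_day   = raw$tmax_day,
    tmin       = raw$tmin,
    tmin_night = raw$tmin_night,
    tmean_app  = apparent_temperature(raw$tmean, dew_mean, formula),
    tmax_app   = apparent_temperature(raw$tmax, dew_max, formula),
    tmin_app   = apparent_temperature(raw$tmin, dew_min, formula)
  )
  attr(out, "fallbacks") <- unique(fallbacks)
  out
}
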