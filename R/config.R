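#' Study configuration
#'
#' Bundles every tunable of the two-stage analysis: the baseline period and
#' warm-season window, the temperature metrics to evaluate, the cross-basis
#' dimensions (maximum lag, exposure knot percentiles, number of log-spaced
#' lag knots), the seasonal-spline density, and the MMT search interval.
#'
#' @param baseline_years integer vector of study years (inclusive range),
#'   default `1995:2015`.
#' @param season_months months kept in the panel, default May-September.
#' @param metrics character vector of metric names to evaluate; defaults to
#'   all eight (see [metric_names()]).
#' @param max_lag maximum lag in days for the cross-basis (default 10).
#' @param exposure_knot_percentiles percentiles of the regional metric
#'   distribution at which the three exposure-spline internal knots sit
#'   (default `c(10, 75, 90)`).
#' @param n_lag_knots number of log-equally-spaced internal lag knots
#'   (default 2).
#' @param seasonal_df_per_year degrees of freedom per year for the seasonal
#'   natural cubic spline `NS(time)` (default 4).
#' @param mmt_search_percentiles closed percentile interval searched for the
#'   minimum mortality temperature (default `c(1, 99)`).
#' @param knot_scope `"country"` (default) pools each country's cities to
#'   place exposure knots on the regional distribution; `"city"` places them
#'   per city (breaks coefficient-space pooling across cities).
#' @param season_pad how outcome rows whose lag window crosses a season start
#'   are handled: `"repeat_first"` (default) pads the window by repeating the
#'   first observed day of the season; `"drop"` excludes those rows from the
#'   fit.
#' @param seasonal_model seasonal/long-term control in the main fit:
#'   `"time_spline"` (default) is the literal natural cubic spline over the
#'   in-season time index with `seasonal_df_per_year` df per year;
#'   `"season_decomposed"` replaces it with a shared day-of-season spline
#'   (`seasonal_df_per_year` df) plus a smooth inter-annual trend spline.
#' @param cv_seasonal_model seasonal control used inside leave-one-year-out
#'   cross-validation (default `"season_decomposed"`: the per-year time
#'   spline cannot be interpolated across a held-out year and is therefore
#'   not usable for out-of-sample prediction; see the methods vignette).
#' @param apparent_formula `"kalkstein"` (default) or `"steadman"`; see
#'   [apparent_temperature()].
#' @param rng_seed integer seed used wherever the pipeline needs randomness
#'   (MMT confidence intervals).
#' @return an object of class `study_config` (a validated list).
#' @export
study_config <- function(baseline_years = 1995:2015,
                         season_months = 5:9,
                         metrics = metric_names(),
                         max_lag = 10L,
                         exposure_knot_percentiles = c(10, 75, 90),
                         n_lag_knots = 2L,
                         seasonal_df_per_year = 4L,
                         mmt_search_percentiles = c(1, 99),
                         knot_scope = c("country", "city"),
                         season_pad = c("repeat_first", "drop"),
                         seasonal_model = c("time_spline", "season_decomposed"),
                         cv_seasonal_model = c("season_decomposed", "time_spline"),
                         apparent_formula = c("kalkstein", "steadman"),
                         rng_seed = 1L) {
  baseline_years <- sort(unique(as.integer(baseline_years)))
  stopifnot(length(baseline_years) >= 1L)
  metrics <- match.arg(metrics, metric_names(), several.ok = TRUE)
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L) stop("max_lag must be >= 1")
  p <- as.numeric(exposure_knot_percentiles)
  if (any(p <= 0) || any(p >= 100) || is.unsorted(p, strictly = TRUE))
    stop("exposure_knot_percentiles must be strictly increasing in (0, 100)")
  seasonal_df_per_year <- as.integer(seasonal_df_per_year)
  if (seasonal_df_per_year < 1L) stop("seasonal_df_per_year must be >= 1")
  mmt <- as.numeric(mmt_search_percentiles)
  stopifnot(length(mmt) == 2L, mmt[1] < mmt[2], mmt[1] >= 0, mmt[2] <= 100)
  structure(list(
    baseline_years = baseline_years,
    season_months = as.integer(season_months),
    metrics = metrics,
    max_lag = max_lag,
    exposure_knot_percentiles = p,
    n_lag_knots = as.integer(n_lag_knots),
    seasonal_df_per_year = seasonal_df_per_year,
    mmt_search_percentiles = mmt,
    knot_scope = match.arg(knot_scope),
    season_pad = match.arg(season_pad),
    seasonal_model = match.arg(seasonal_model),
    cv_seasonal_model = match.arg(cv_seasonal_model),
    apparent_formula = match.arg(apparent_formula),
    rng_seed = as.integer(rng_seed)
  ), class = "study_config")
}

#' Read a study configuration from YAML
#'
#' The YAML file mirrors [study_config()] field for field; absent fields keep
#' their defaults. `baseline_years` may be given as a two-element
#' `[first, last]` range.
#'
#' @param path path to a YAML file.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  if (!is.null(raw$baseline_years) && length(raw$baseline_years) == 2L)
    raw$baseline_years <- raw$baseline_years[1]:raw$baseline_years[2]
  do.call(study_config, raw)
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat("  years   :", min(x$baseline_years), "-", max(x$baseline_years), "\n")
  cat("  months  :", paste(x$season_months, collapse = ","), "\n")
  cat("  metrics :", paste(x$metrics, collapse = ", "), "\n")
  cat("  cross-basis: max_lag", x$max_lag,
      "| exposure knots at P", paste(x$exposure_knot_percentiles, collapse = "/"),
      "| ", x$n_lag_knots, "log lag knots\n")
  cat("  seasonal df/year:", x$seasonal_df_per_year,
      "| MMT search P", paste(x$mmt_search_percentiles, collapse = "-"), "\n")
  invisible(x)
}
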