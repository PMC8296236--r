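#' Ground truth for the synthetic panel generator
#'
#' States the world the generator draws from: a single driver metric (tmean
#' by default) whose lagged exceedances above a known threshold raise
#' mortality log-linearly, seven companion metrics correlated with the
#' driver, and overdispersed daily counts with seasonal and day-of-week
#' structure. Defaults emulate a mid-size European city over the 1995-2015
#' warm seasons: ~30 deaths/day, a heat effect of 3% per degree C above the
#' 70th driver percentile cumulated over lags 0-10 with geometrically
#' decaying weights, quasi-Poisson overdispersion 1.5, and cross-metric
#' correlation 0.9 (the "high correlation between temperature measures"
#' regime in which metric selection is genuinely hard).
#'
#' @param driver_metric the metric that truly drives mortality.
#' @param threshold_percentile percentile of the driver above which heat
#'   kills (the true MMT sits at this percentile), default 70.
#' @param slope log-RR per degree C above threshold, cumulated over the lag
#'   window (default 0.03).
#' @param lag_ratio geometric decay ratio of the lag weights over lags
#'   0..max_lag (default 0.6); weights are normalized to sum to 1.
#' @param max_lag maximum lag of the true effect (default 10).
#' @param baseline mean daily deaths (default 30).
#' @param overdispersion variance/mean ratio of daily counts (default 1.5;
#'   1 = Poisson).
#' @param dow_effects 7 multiplicative day-of-week effects (Mon..Sun).
#' @param seasonal_amplitude amplitude of the log-scale seasonal mortality
#'   term (default 0.05; mortality dips mid-summer net of heat).
#' @param metric_correlation target Pearson correlation between the driver
#'   and each companion metric (default 0.9).
#' @param temp_mean,temp_amplitude warm-season temperature climatology:
#'   annual-cycle mean level and amplitude, degrees C.
#' @param ar_rho,ar_sd AR(1) day-to-day temperature noise: autocorrelation
#'   and marginal standard deviation.
#' @param n_years seasons generated (default 21), starting at `first_year`.
#' @param seed RNG seed.
#' @return object of class `generator_truth`.
#' @export
generator_truth <- function(driver_metric = "tmean",
                            threshold_percentile = 70,
                            slope = 0.03,
                            lag_ratio = 0.6,
                            max_lag = 10L,
                            baseline = 30,
                            overdispersion = 1.5,
                            dow_effects = c(1, 1, 1, 1, 1, 0.98, 0.97),
                            seasonal_amplitude = 0.05,
                            metric_correlation = 0.9,
                            temp_mean = 18, temp_amplitude = 6,
                            ar_rho = 0.7, ar_sd = 2.5,
                            n_years = 21L, first_year = 1995L,
                            seed = 1L) {
  stopifnot(driver_metric %in% metric_names(),
            threshold_percentile > 0, threshold_percentile < 100,
            overdispersion >= 1, length(dow_effects) == 7L,
            metric_correlation >= 0, metric_correlation < 1,
            lag_ratio > 0, n_years >= 1)
  w <- lag_ratio^(0:max_lag)
  structure(list(driver_metric = driver_metric,
                 threshold_percentile = threshold_percentile,
                 slope = slope, lag_weights = w / sum(w),
                 max_lag = as.integer(max_lag),
                 baseline = baseline, overdispersion = overdispersion,
                 dow_effects = dow_effects,
                 seasonal_amplitude = seasonal_amplitude,
                 metric_correlation = metric_correlation,
                 temp_mean = temp_mean, temp_amplitude = temp_amplitude,
                 ar_rho = ar_rho, ar_sd = ar_sd,
                 n_years = as.integer(n_years),
                 first_year = as.integer(first_year),
                 seed = as.integer(seed)),
            class = "generator_truth")
}

# Season-blocked lagged hinge sum: sum_l w_l * max(0, x_{t-l} - thr),
# windows padded by repeating the season's first value (matching the
# analysis-side convention).
lagged_hinge <- function(x, thr, weights, groups) {
  L <- length(weights) - 1L
  Q <- lag_matrix(x, L, groups, pad = TRUE)$values
  drop(pmax(Q - thr, 0) %*% weights)
}

#' Generate one synthetic city panel
#'
#' Temperatures follow a seasonal sinusoid (peak late July) plus AR(1)
#' noise; the companion metrics are affine shifts of the driver with
#' correlated noise calibrated to `metric_correlation`, clamped so that
#' tmin <= tmean <= tmax on every day; a correlated dew-point series makes
#' the three apparent metrics derivable through [derive_metrics()]. Deaths
#' are negative-binomial with variance `overdispersion * mean` and log-mean
#' `log(baseline) + seasonal + DOW + sum_l w_l * slope * max(0, x_{t-l} -
#' threshold)`, where the threshold is the configured percentile of this
#' realization's driver series. Deterministic given `seed`.
#'
#' @param truth a [generator_truth()].
#' @param city_id identifier for the generated city.
#' @param country_id country identifier (default `"SIM"`).
#' @param seed RNG seed; defaults to `truth$seed`.
#' @return a [city_panel()] carrying `meta$truth` (threshold, slope,
#'   driver) and `meta$truth_hash` for downstream ground-truth audits.
#' @export
generate_panel <- function(truth, city_id = "city1", country_id = "SIM",
                           seed = truth$seed) {
  stopifnot(inherits(truth, "generator_truth"))
  set.seed(seed)
  years <- truth$first_year + seq_len(truth$n_years) - 1L
  dates <- do.call(c, lapply(years, function(y)
    seq(as.Date(sprintf("%d-05-01", y)), as.Date(sprintf("%d-09-30", y)),
        by = "day")))
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  yr <- as.integer(format(dates, "%Y"))

  # season-blocked AR(1) with marginal sd `sd`
  ar1 <- function(sd, rho = truth$ar_rho) {
    innov_sd <- sd * sqrt(1 - rho^2)
    a <- numeric(n)
    for (y in years) {
      ix <- which(yr == y)
      e <- stats::rnorm(length(ix), 0, innov_sd)
      a[ix[1]] <- stats::rnorm(1, 0, sd)
      for (t in seq_along(ix)[-1])
        a[ix[t]] <- rho * a[ix[t - 1]] + e[t]
    }
    a
  }

  # driver temperature: annual cycle peaking July 24 + AR(1) weather noise
  driver <- truth$temp_mean +
    truth$temp_amplitude * cos(2 * pi * (doy - 205) / 365) + ar1(truth$ar_sd)

  # companion metrics: affine shift + noise at the target daily correlation;
  # the noise persists on the driver's own AR(1) timescale (inter-metric
  # spreads ride multi-day weather regimes, they do not re-draw every day)
  rho <- truth$metric_correlation
  sigma <- stats::sd(driver) * sqrt(1 / rho^2 - 1)
  shifted <- function(offset) offset + ar1(sigma)
  d_max  <- pmax(0.3, shifted(5.5)); d_min  <- pmax(0.3, shifted(5.5))
  d_maxd <- pmax(0.2, shifted(5.0)); d_minn <- pmax(0.4, shifted(6.0))
  raw <- data.frame(
    tmean = driver,
    tmax = driver + d_max,
    tmax_day = driver + d_maxd,
    tmin = driver - d_min,
    tmin_night = driver - d_minn
  )
  # dew point rides the minimum temperature; clamped below saturation bound
  dew <- raw$tmin - 2 + ar1(1.5)
  raw$dewpoint_mean <- pmin(dew, raw$tmin + 4.9)
  metrics <- derive_metrics(raw)

  x <- metrics[[truth$driver_metric]]
  thr <- stats::quantile(x, truth$threshold_percentile / 100,
                         names = FALSE, type = 7)
  dow <- as.integer(format(dates, "%u"))
  log_mu <- log(truth$baseline) +
    truth$seasonal_amplitude * cos(2 * pi * doy / 365) +
    log(truth$dow_effects[dow]) +
    truth$slope * lagged_hinge(x, thr, truth$lag_weights, yr)
  mu <- exp(log_mu)
  deaths <- if (truth$overdispersion > 1 + 1e-9) {
    stats::rnbinom(n, size = mu / (truth$overdispersion - 1), mu = mu)
  } else {
    stats::rpois(n, mu)
  }

  meta <- list(truth = list(threshold = thr,
                            threshold_percentile = truth$threshold_percentile,
                            slope = truth$slope,
                            driver_metric = truth$driver_metric),
               truth_hash = panel_hash(deaths, x))
  city_panel(city_id, country_id, dates, deaths, metrics, meta)
}

panel_hash <- function(deaths, x)
  sprintf("%.10e", sum(deaths) + sum(round(x, 6)))

#' Generate a multi-city synthetic country
#'
#' Cities share the climatology and true effect but draw independent
#' realizations (seeds `seed + 1 .. seed + n_cities`) with mildly varying
#' baselines.
#'
#' @param truth a [generator_truth()].
#' @param n_cities number of cities.
#' @param country_id country identifier.
#' @return list of [city_panel()]s.
#' @export
generate_country <- function(truth, n_cities = 2L, country_id = "SIM") {
  lapply(seq_len(n_cities), function(i) {
    t_i <- truth
    t_i$baseline <- truth$baseline * (0.8 + 0.1 * (i %% 5))
    generate_panel(t_i, city_id = sprintf("%s_city%d", country_id, i),
                   country_id = country_id, seed = truth$seed + i)
  })
}

#' Ground-truth attributable fractions for a generated panel
#'
#' Evaluates the attributable-fraction identities with the generator's
#' exact cumulative relative risk RR_i = exp(slope * max(0, T_i -
#' threshold)) and exact MMT (= the threshold), giving the true HAF, EHAF
#' and MHAF of that realization -- the oracle the fitted pipeline is judged
#' against. Warns if the panel does not carry this truth's hash.
#'
#' @param truth the [generator_truth()] that generated the panel.
#' @param panel the generated [city_panel()].
#' @return object of class `attribution_result` (no per-day components).
#' @export
true_attribution <- function(truth, panel) {
  stopifnot(inherits(truth, "generator_truth"), inherits(panel, "city_panel"))
  x <- panel$data[[truth$driver_metric]]
  if (!identical(panel$meta$truth_hash, panel_hash(panel$data$deaths, x)))
    warning("panel does not match this generator truth (hash mismatch)")
  thr <- stats::quantile(x, truth$threshold_percentile / 100,
                         names = FALSE, type = 7)
  p90 <- stats::quantile(x, 0.9, names = FALSE, type = 7)
  rr <- exp(truth$slope * pmax(x - thr, 0))
  core <- attr_core(panel$data$deaths, x, rr, thr, p90)
  structure(c(core[c("haf", "ehaf", "mhaf")],
              list(mmt = thr, p90 = p90, mmt_above_p90 = thr > p90,
                   numerators = core[c("num_haf", "num_ehaf", "num_mhaf")],
                   denom = core$denom, n_missing_temp = core$n_missing_temp,
                   components = NULL,
                   city_id = panel$city_id,
                   metric = truth$driver_metric)),
            class = "attribution_result")
}
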