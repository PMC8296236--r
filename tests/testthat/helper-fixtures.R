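# Shared fixtures: small panels and curve constructors built in code.

# A minimal in-season panel with given deaths/temps (single season).
toy_panel <- function(deaths, temps, year = 2000, city = "toy",
                      metric = "tmean") {
  n <- length(deaths)
  dates <- seq(as.Date(sprintf("%d-06-01", year)), by = "day", length.out = n)
  metrics <- stats::setNames(data.frame(temps), metric)
  city_panel(city, "TT", dates, deaths, metrics)
}

# Exposure spline spec over a temperature range with the canonical
# P10/75/90-style interior knots.
toy_exposure_spec <- function(lo = 10, hi = 35, knots = c(15, 25, 30)) {
  spline_spec(knots, boundary = c(lo, hi), intercept = FALSE)
}

# A reduced_curve with given coefficients on a toy exposure spec.
toy_curve <- function(theta, spec = toy_exposure_spec(), vcov = NULL,
                      city = "toy", metric = "tmean") {
  if (is.null(vcov)) vcov <- diag(1e-4, length(theta))
  structure(list(theta = theta, vcov = vcov, exposure_spec = spec,
                 city_id = city, metric = metric),
            class = "reduced_curve")
}

# Scale a direction vector so the curve's RR at temperature `at` (centered
# at `center`) equals `rr`.
curve_with_rr <- function(rr, at, center, spec = toy_exposure_spec(),
                          direction = NULL) {
  if (is.null(direction)) direction <- rep(1, spec$df)
  gap <- drop((ns_basis(at, spec) - ns_basis(center, spec)) %*% direction)
  toy_curve(direction * log(rr) / gap, spec = spec)
}

# Small synthetic truth used where full 21-season scale is unnecessary.
quick_truth <- function(seed, n_years = 4, baseline = 20, ...) {
  generator_truth(seed = seed, n_years = n_years, baseline = baseline, ...)
}
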