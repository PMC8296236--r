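#' Relative risk along the cumulative exposure-response curve
#'
#' Evaluates RR(x) = exp((b(x) - b(center)) . theta), with b the exposure
#' natural-spline basis and theta the lag-cumulated coefficients, so RR is
#' the mortality ratio at temperature x versus the centering temperature,
#' cumulated over the full lag window. RR(center) = 1 exactly. Temperatures
#' beyond the basis boundary knots are evaluated by the natural-spline
#' linear extrapolation and flagged in the `"extrapolated"` attribute.
#'
#' @param curve a `reduced_curve` (from [reduce_fit()], [blup()], or the
#'   pooled mean wrapped via [pooled_as_curve()]).
#' @param temps temperatures at which to evaluate RR, degrees C.
#' @param center centering temperature (the MMT once located), degrees C.
#' @return numeric vector of relative risks.
#' @export
predict_rr <- function(curve, temps, center) {
  stopifnot(inherits(curve, "reduced_curve"), length(center) == 1L,
            is.finite(center))
  spec <- curve$exposure_spec
  b <- ns_basis(temps, spec)
  b0 <- ns_basis(center, spec)
  rr <- exp(drop((b - matrix(b0, nrow(b), ncol(b), byrow = TRUE)) %*%
                   curve$theta))
  extra <- which(temps < spec$boundary[1] | temps > spec$boundary[2])
  attr(rr, "extrapolated") <- extra
  rr
}

#' Wrap the pooled mean as a curve
#'
#' @param pooled a [meta_fit()] result.
#' @return a `reduced_curve` carrying the pooled coefficients.
#' @export
pooled_as_curve <- function(pooled) {
  stopifnot(inherits(pooled, "pooled_curves"))
  structure(list(theta = pooled$mu, vcov = pooled$vcov_mu,
                 exposure_spec = pooled$exposure_spec,
                 city_id = "(pooled)", metric = pooled$curves[[1]]$metric),
            class = "reduced_curve")
}

#' Locate the minimum mortality temperature (MMT)
#'
#' The MMT is the temperature at which temperature-attributable mortality is
#' smallest: the argmin of the cumulative exposure-response curve over a
#' dense grid (default 1000 points) spanning the search percentiles of the
#' observed metric distribution. The minimum mortality percentile (MMP) is
#' the empirical percentile of the MMT under the same distribution. An
#' optional empirical confidence interval resamples coefficient vectors
#' from N(theta, vcov) and takes the 2.5/97.5 quantiles of the per-draw
#' argmins.
#'
#' @param curve a `reduced_curve` (centering is irrelevant to the argmin).
#' @param temps observed metric values defining the search distribution.
#' @param search percentile interval to search (default `c(1, 99)`).
#' @param n_grid grid resolution (default 1000).
#' @param ci compute an empirical interval (default `FALSE`)?
#' @param n_draws Monte Carlo draws for the interval (default 1000).
#' @param seed RNG seed for the draws.
#' @return object of class `mmt_result`: `mmt`, `mmp`, `search`, `flat`
#'   flag, and `ci` (NULL unless requested).
#' @export
find_mmt <- function(curve, temps, search = c(1, 99), n_grid = 1000L,
                     ci = FALSE, n_draws = 1000L, seed = NULL) {
  stopifnot(inherits(curve, "reduced_curve"))
  temps <- temps[is.finite(temps)]
  if (!length(temps)) stop("no finite temperatures to search over")
  rng <- stats::quantile(temps, search / 100, names = FALSE, type = 7)
  grid <- seq(rng[1], rng[2], length.out = n_grid)
  B <- ns_basis(grid, curve$exposure_spec)
  vals <- drop(B %*% curve$theta)
  flat <- diff(range(vals)) < 1e-12
  mmt <- if (flat) grid[ceiling(n_grid / 2)] else grid[which.min(vals)]
  out <- list(mmt = mmt,
              mmp = 100 * stats::ecdf(temps)(mmt),
              search = search, flat = flat, ci = NULL)
  if (ci) {
    if (!is.null(seed)) set.seed(seed)
    draws <- MASS::mvrnorm(n_draws, curve$theta, curve$vcov)
    mins <- grid[max.col(-draws %*% t(B), ties.method = "first")]
    out$ci <- stats::quantile(mins, c(0.025, 0.975), names = FALSE)
  }
  class(out) <- "mmt_result"
  out
}

#' @export
print.mmt_result <- function(x, ...) {
  cat(sprintf("MMT %.2f degC (MMP %.1f%%)%s\n", x$mmt, x$mmp,
              if (x$flat) " [flat curve]" else ""))
  if (!is.null(x$ci))
    cat(sprintf("  95%% empirical CI: %.2f - %.2f degC\n", x$ci[1], x$ci[2]))
  invisible(x)
}

# Shared attributable-fraction arithmetic over pre-computed daily RRs.
# A = days with observed deaths; B/C/D subset A by temperature.
attr_core <- function(deaths, temps, rr, mmt, p90) {
  A <- !is.na(deaths)
  total <- sum(deaths[A])
  if (total <= 0) stop("total deaths are zero; attributable fraction undefined")
  contrib <- deaths * (1 - 1 / rr)
  inB <- A & !is.na(temps) & temps >= mmt
  inC <- A & !is.na(temps) & temps >= p90
  inD <- A & !is.na(temps) & temps >= mmt & temps < p90
  list(haf = 100 * sum(contrib[inB]) / total,
       ehaf = 100 * sum(contrib[inC]) / total,
       mhaf = 100 * sum(contrib[inD]) / total,
       num_haf = sum(contrib[inB]), num_ehaf = sum(contrib[inC]),
       num_mhaf = sum(contrib[inD]), denom = total,
       n_missing_temp = sum(A & is.na(temps)))
}

#' Heat-attributable fractions (HAF, EHAF, MHAF)
#'
#' Computes the fraction of total mortality attributable to heat:
#' \deqn{HAF = \sum_{i: T_i \ge MMT} m_i (1 - 1/RR_i) \Big/ \sum_{j} m_j}
#' with `m_i` the daily deaths, `T_i` the daily metric value and `RR_i` the
#' cumulative relative risk at `T_i` versus the MMT. EHAF restricts the
#' numerator to extreme-heat days (`T_i >= P90`, the city's own warm-season
#' 90th percentile) and MHAF to moderate-heat days (`MMT <= T_i < P90`);
#' when `MMT <= P90` these partition the heat days, so HAF = EHAF + MHAF.
#' Fractions are reported in percent. Days with missing deaths are outside
#' the study set A; days with missing temperature contribute to the
#' denominator only and are counted in the audit field.
#'
#' @param panel a [city_panel()].
#' @param metric metric name (a column of the panel).
#' @param curve the city's curve (BLUP by default in the pipeline).
#' @param mmt the minimum mortality temperature used as the RR reference.
#' @param p90 extreme-heat threshold; default the 90th percentile of the
#'   panel's observed metric values.
#' @return object of class `attribution_result`: `haf`, `ehaf`, `mhaf`
#'   (percent), `mmt`, `p90`, per-day `components` for audit, and
#'   `mmt_above_p90` flag.
#' @export
attributable_fractions <- function(panel, metric, curve, mmt, p90 = NULL) {
  stopifnot(inherits(panel, "city_panel"),
            metric %in% names(panel$data))
  temps <- panel$data[[metric]]
  deaths <- panel$data$deaths
  if (is.null(p90))
    p90 <- stats::quantile(temps[is.finite(temps)], 0.9, names = FALSE,
                           type = 7)
  rr <- rep(NA_real_, length(temps))
  ok <- is.finite(temps)
  rr[ok] <- predict_rr(curve, temps[ok], center = mmt)
  core <- attr_core(deaths, temps, rr, mmt, p90)
  structure(c(core[c("haf", "ehaf", "mhaf")],
              list(mmt = mmt, p90 = p90,
                   mmt_above_p90 = mmt > p90,
                   numerators = core[c("num_haf", "num_ehaf", "num_mhaf")],
                   denom = core$denom,
                   n_missing_temp = core$n_missing_temp,
                   components = data.frame(date = panel$data$date,
                                           deaths = deaths, temp = temps,
                                           rr = rr),
                   city_id = panel$city_id, metric = metric)),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("%s / %s: HAF %.2f%% (EHAF %.2f%% + MHAF %.2f%%), MMT %.2f degC, P90 %.2f degC\n",
              x$city_id, x$metric, x$haf, x$ehaf, x$mhaf, x$mmt, x$p90))
  invisible(x)
}
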