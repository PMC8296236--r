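#' Assemble the city-level design matrix
#'
#' Columns, in order: intercept | cross-basis block | day-of-week indicators
#' (6 columns, Monday reference) | seasonal block. Under the default
#' `"time_spline"` model the seasonal block is a natural cubic spline over
#' the in-season time index with `seasonal_df_per_year` degrees of freedom
#' per year of data, evaluated on the full panel's time index with boundary
#' knots at the panel endpoints and internal knots at quantiles of the
#' *fitted* rows' time index. Under `"season_decomposed"` it is a shared
#' day-of-season spline (`seasonal_df_per_year` df, identical shape every
#' year) plus a low-df natural-spline trend in calendar year -- the form
#' that remains predictable for a year held out of the fit (see the methods
#' vignette).
#'
#' The default row mask keeps rows with an observed death count and a
#' complete cross-basis row; under `season_pad = "drop"` season-start rows
#' with padded lag windows are excluded as well.
#'
#' @param panel a [city_panel()].
#' @param cb a [build_cross_basis()] result built from the same panel.
#' @param config a [study_config()].
#' @param fit_rows optional logical mask of rows eligible for fitting
#'   (e.g. the training years of a cross-validation fold); intersected with
#'   the validity mask.
#' @param seasonal_model overrides `config$seasonal_model`.
#' @return object of class `design_matrix`: `X` (n x p), `layout` (column
#'   indices per block), `row_mask`.
#' @export
build_design <- function(panel, cb, config, fit_rows = NULL,
                         seasonal_model = config$seasonal_model) {
  stopifnot(inherits(panel, "city_panel"), inherits(cb, "cross_basis"))
  d <- panel$data
  n <- nrow(d)
  stopifnot(nrow(cb$values) == n)

  mask <- !is.na(d$deaths) & stats::complete.cases(cb$values)
  if (config$season_pad == "drop") mask <- mask & cb$valid_row_mask
  if (!is.null(fit_rows)) mask <- mask & fit_rows
  if (sum(mask) < 2L) stop("fewer than 2 fittable rows after masking")

  dow <- matrix(0, n, 6L,
                dimnames = list(NULL, paste0("dow", 2:7)))
  for (k in 2:7) dow[d$dow == k, k - 1L] <- 1

  n_years <- length(unique(d$year))
  quantile_knots <- function(v_fit, df, boundary) {
    kn <- stats::quantile(v_fit, seq_len(df - 1L) / df, names = FALSE,
                          type = 7)
    if (anyDuplicated(kn)) stop("seasonal spline knots are not distinct")
    spline_spec(kn, boundary = boundary, intercept = FALSE)
  }

  trend <- NULL
  if (seasonal_model == "time_spline") {
    seas_spec <- quantile_knots(d$time_index[mask],
                                config$seasonal_df_per_year * n_years,
                                range(d$time_index))
    seas <- ns_basis(d$time_index, seas_spec)
  } else {
    doy <- as.integer(format(d$date, "%j"))
    seas_spec <- quantile_knots(doy[mask], config$seasonal_df_per_year,
                                range(doy))
    seas <- ns_basis(doy, seas_spec)
    # inter-annual trend: about one df per 7 years, capped below the number
    # of distinct years actually fitted (a CV fold removes one)
    n_fit_years <- length(unique(d$year[mask]))
    df_trend <- if (n_fit_years <= 1L) 0L else
      min(n_fit_years - 1L, max(2L, 1L + n_years %/% 7L))
    if (df_trend > 0L) {
      tr_spec <- if (df_trend == 1L)
        spline_spec(numeric(0), range(d$year)) else
        quantile_knots(d$year[mask], df_trend, range(d$year))
      trend <- ns_basis(d$year, tr_spec)
      colnames(trend) <- paste0("trend", seq_len(ncol(trend)))
    }
  }
  colnames(seas) <- paste0("seas", seq_len(ncol(seas)))

  X <- cbind(`(Intercept)` = 1, cb$values, dow, seas)
  if (!is.null(trend)) X <- cbind(X, trend)
  p_cb <- ncol(cb$values)
  layout <- list(intercept = 1L,
                 cb = 1L + seq_len(p_cb),
                 dow = 1L + p_cb + 1:6,
                 seasonal = 1L + p_cb + 6L + seq_len(ncol(seas)))
  if (!is.null(trend))
    layout$trend <- 1L + p_cb + 6L + ncol(seas) + seq_len(ncol(trend))

  qx <- qr(X[mask, , drop = FALSE])
  if (qx$rank < ncol(X)) {
    dropped <- qx$pivot[seq.int(qx$rank + 1L, ncol(X))]
    blocks <- vapply(dropped, function(j)
      names(layout)[vapply(layout, function(ix) j %in% ix, logical(1))][1],
      character(1))
    stop("design matrix rank deficient in block(s): ",
         paste(unique(blocks), collapse = ", "))
  }

  structure(list(X = X, layout = layout, row_mask = mask,
                 seasonal_spec = seas_spec),
            class = "design_matrix")
}

#' Fit a quasi-Poisson log-linear model by IRLS
#'
#' Iteratively reweighted least squares with the canonical log link, run to
#' relative coefficient change below 1e-9 (at most 100 iterations). Point
#' estimates are identical to the Poisson maximum-likelihood fit; the
#' covariance is scaled by the Pearson chi-square dispersion
#' `sum((y - mu)^2 / mu) / (n - p)`, the quasi-likelihood correction for
#' overdispersed counts.
#'
#' @param y non-negative integer counts.
#' @param design a [build_design()] result, or a plain numeric matrix (then
#'   all rows are fitted).
#' @return object of class `qp_fit`: `beta`, `vcov`, `dispersion`,
#'   `n_fitted`, `converged`, `fitted` (on the fitted rows), `layout`.
#' @export
fit_quasipoisson <- function(y, design) {
  if (is.matrix(design))
    design <- structure(list(X = design, layout = list(all = seq_len(ncol(design))),
                             row_mask = rep(TRUE, nrow(design))),
                        class = "design_matrix")
  stopifnot(inherits(design, "design_matrix"))
  mask <- design$row_mask
  X <- design$X[mask, , drop = FALSE]
  yy <- y[mask]
  if (any(!is.finite(yy)) || any(yy < 0)) stop("y must be non-negative on fitted rows")
  n <- nrow(X); p <- ncol(X)

  mu <- yy + 0.5
  eta <- log(mu)
  beta <- NULL
  converged <- FALSE
  trace <- numeric(0)
  for (it in seq_len(100L)) {
    w <- mu
    z <- eta + (yy - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    if (anyNA(beta_new)) stop("IRLS hit a rank-deficient weighted design")
    if (!is.null(beta)) {
      delta <- max(abs(beta_new - beta) / pmax(abs(beta), 1e-8))
      trace <- c(trace, delta)
      if (delta < 1e-9) { beta <- beta_new; converged <- TRUE; break }
    }
    beta <- beta_new
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    if (any(!is.finite(mu))) stop("IRLS diverged: non-finite fitted means")
  }
  if (!converged)
    stop("IRLS did not converge in 100 iterations; trace: ",
         paste(signif(utils::tail(trace, 5), 3), collapse = ", "))

  dispersion <- sum((yy - mu)^2 / mu) / (n - p)
  # (X' W X)^{-1} from the pivoted QR of sqrt(w) X
  R <- qr.R(fit$qr)
  piv <- fit$qr$pivot
  V <- matrix(NA_real_, p, p)
  V[piv, piv] <- chol2inv(R)
  vcov <- dispersion * V
  dimnames(vcov) <- list(colnames(X), colnames(X))

  structure(list(beta = beta, vcov = vcov, dispersion = dispersion,
                 n_fitted = n, converged = converged, fitted = mu,
                 layout = design$layout),
            class = "qp_fit")
}

#' Predict expected daily deaths
#'
#' @param fit a [fit_quasipoisson()] result.
#' @param X_new numeric matrix whose columns match the fitted design layout
#'   (e.g. validation-year rows of the same [build_design()] matrix).
#' @return expected counts `exp(X_new %*% beta)`.
#' @export
predict_deaths <- function(fit, X_new) {
  stopifnot(inherits(fit, "qp_fit"))
  if (!is.matrix(X_new)) X_new <- matrix(X_new, nrow = 1)
  if (ncol(X_new) != length(fit$beta))
    stop("X_new has ", ncol(X_new), " columns; fit expects ", length(fit$beta))
  drop(exp(X_new %*% fit$beta))
}

#' Reduce a fitted cross-basis to its cumulative exposure-response curve
#'
#' Extracts the cross-basis coefficient block and covariance from a city
#' fit and collapses them over the lag dimension with
#' [lag_cumulation_map()], yielding the overall-cumulative
#' exposure-response coefficients theta (length df_exp) and covariance --
#' the objects that enter the second-stage meta-analysis.
#'
#' @param fit a [fit_quasipoisson()] result whose design contained a `cb`
#'   block.
#' @param spec the [cross_basis_spec()] used to build that block.
#' @param city_id,metric identifiers carried on the curve.
#' @return object of class `reduced_curve`: `theta`, `vcov`,
#'   `exposure_spec`, `city_id`, `metric`.
#' @export
reduce_fit <- function(fit, spec, city_id = NA_character_,
                       metric = NA_character_) {
  stopifnot(inherits(fit, "qp_fit"), inherits(spec, "cross_basis_spec"))
  ix <- fit$layout$cb
  if (is.null(ix)) stop("fit has no cross-basis block")
  M <- lag_cumulation_map(spec)
  beta <- fit$beta[ix]
  V <- fit$vcov[ix, ix, drop = FALSE]
  structure(list(theta = drop(crossprod(M, beta)),
                 vcov = crossprod(M, V %*% M),
                 exposure_spec = spec$exposure_spec,
                 city_id = city_id, metric = metric),
            class = "reduced_curve")
}
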