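#' Natural cubic spline basis specification
#'
#' Fixes the internal knots, boundary knots and intercept convention of a
#' natural-cubic-spline basis so the identical basis can be re-evaluated at
#' arbitrary points (prediction, reduction, MMT search).
#'
#' @param knots internal knot locations, strictly increasing.
#' @param boundary length-2 boundary knots; the basis is linear beyond them.
#' @param intercept include the constant column? The exposure basis uses
#'   `FALSE` (the model has its own intercept); the lag basis uses `TRUE`.
#' @return object of class `spline_spec` with a `df` field
#'   (`length(knots) + 1 + intercept`).
#' @export
spline_spec <- function(knots, boundary, intercept = FALSE) {
  knots <- as.numeric(knots)
  boundary <- as.numeric(boundary)
  stopifnot(length(boundary) == 2L, boundary[1] < boundary[2])
  if (length(knots)) {
    if (is.unsorted(knots, strictly = TRUE))
      stop("internal knots must be strictly increasing")
    if (min(knots) <= boundary[1] || max(knots) >= boundary[2])
      stop("internal knots must lie strictly inside the boundary knots")
  }
  structure(list(knots = knots, boundary = boundary,
                 intercept = isTRUE(intercept),
                 df = length(knots) + 1L + isTRUE(intercept)),
            class = "spline_spec")
}

#' Evaluate a natural cubic spline basis
#'
#' Returns the n x df natural-spline design for `x` under `spec`; the basis
#' is linear beyond the boundary knots. `NA` entries are treated as missing
#' markers and propagate to `NA` rows; `NaN`/`Inf` are hard errors.
#'
#' @param x numeric vector of evaluation points.
#' @param spec a [spline_spec()].
#' @return matrix with `spec$df` columns.
#' @export
ns_basis <- function(x, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  bad <- which(is.nan(x) | is.infinite(x))
  if (length(bad))
    stop("non-finite values in x at indices: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  out <- matrix(NA_real_, length(x), spec$df)
  ok <- !is.na(x)
  if (any(ok)) {
    out[ok, ] <- splines::ns(x[ok],
                             knots = if (length(spec$knots)) spec$knots,
                             Boundary.knots = spec$boundary,
                             intercept = spec$intercept)
  }
  colnames(out) <- paste0("b", seq_len(spec$df))
  out
}

#' Log-equally-spaced internal lag knots
#'
#' Places `n_knots` internal knots at `max_lag^(k/(n_knots+1))`,
#' k = 1..n_knots: equally spaced on the log scale between lag 1 and
#' `max_lag`. With the default lag 10 and two knots this gives
#' 10^(1/3) and 10^(2/3) (about 2.154 and 4.642 days), concentrating
#' resolution at short lags where acute heat effects and harvesting live.
#'
#' @param max_lag maximum lag in days (>= 2).
#' @param n_knots number of internal knots (>= 1).
#' @return numeric vector of knot positions on the lag scale.
#' @export
log_lag_knots <- function(max_lag, n_knots) {
  stopifnot(max_lag >= 2, n_knots >= 1)
  max_lag^(seq_len(n_knots) / (n_knots + 1))
}

#' Cross-basis specification
#'
#' Pairs an exposure spline (knots at regional temperature percentiles, no
#' intercept) with a lag spline (log-spaced knots over 0..max_lag, with
#' intercept) into the tensor-product design of a distributed lag nonlinear
#' model.
#'
#' @param exposure_spec [spline_spec()] for the exposure dimension.
#' @param lag_spec [spline_spec()] for the lag dimension.
#' @param max_lag maximum lag in days.
#' @return object of class `cross_basis_spec` with `df = df_exp * df_lag`.
#' @export
cross_basis_spec <- function(exposure_spec, lag_spec, max_lag) {
  stopifnot(inherits(exposure_spec, "spline_spec"),
            inherits(lag_spec, "spline_spec"), max_lag >= 1)
  structure(list(exposure_spec = exposure_spec, lag_spec = lag_spec,
                 max_lag = as.integer(max_lag),
                 df = exposure_spec$df * lag_spec$df),
            class = "cross_basis_spec")
}

#' Default cross-basis specification from a metric distribution
#'
#' Places the exposure knots at the configured percentiles (default
#' 10th/75th/90th) of the supplied "regional" metric values, boundary knots
#' at the observed range, and the lag knots log-spaced over 0..max_lag.
#'
#' @param values pooled metric values defining the regional distribution
#'   (typically all of one country's cities over the baseline warm seasons).
#' @param config a [study_config()].
#' @return a [cross_basis_spec()].
#' @export
default_cross_basis_spec <- function(values, config) {
  v <- values[is.finite(values)]
  if (!length(v)) stop("no finite metric values to place knots on")
  ek <- stats::quantile(v, config$exposure_knot_percentiles / 100,
                        names = FALSE, type = 7)
  if (is.unsorted(ek, strictly = TRUE))
    stop("degenerate metric distribution: exposure knots are not distinct")
  exposure <- spline_spec(ek, boundary = range(v), intercept = FALSE)
  lag <- spline_spec(log_lag_knots(config$max_lag, config$n_lag_knots),
                     boundary = c(0, config$max_lag), intercept = TRUE)
  cross_basis_spec(exposure, lag, config$max_lag)
}

# Lagged exposure matrix: column l+1 holds x_{t-l}. Lags never cross a
# group (season) boundary; the window is padded by repeating the group's
# first value, or filled with NA when pad = FALSE.
lag_matrix <- function(x, max_lag, groups = NULL, pad = TRUE) {
  n <- length(x)
  if (is.null(groups)) groups <- rep(1L, n)
  stopifnot(length(groups) == n)
  Q <- matrix(NA_real_, n, max_lag + 1L)
  padded <- logical(n)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    xi <- x[idx]
    m <- length(xi)
    for (l in 0:max_lag) {
      lagged <- c(rep(if (pad) xi[1] else NA_real_, min(l, m)),
                  xi[seq_len(max(m - l, 0))])
      Q[idx, l + 1L] <- lagged[seq_len(m)]
    }
    padded[idx[seq_len(min(max_lag, m))]] <- TRUE
  }
  list(values = Q, padded = padded)
}

#' Build the cross-basis matrix for a metric series
#'
#' Row t, column (j,k) holds
#' \deqn{\sum_{l=0}^{L} B^{exp}_j(x_{t-l})\, B^{lag}_k(l),}
#' the tensor-product encoding of the lagged nonlinear temperature effect.
#' Columns are exposure-major: all lag columns of exposure basis 1, then of
#' exposure basis 2, and so on. Lag windows never cross a season boundary:
#' the first `max_lag` days of each season use a window padded by repeating
#' the season's first observed value (`pad = TRUE`, default) or are left
#' `NA` (`pad = FALSE`); padded rows are flagged in `valid_row_mask`.
#'
#' @param x metric values of one city's panel, in date order.
#' @param spec a [cross_basis_spec()].
#' @param groups season block labels (e.g. year), same length as `x`;
#'   `NULL` treats the series as one contiguous block.
#' @param pad pad season-start lag windows (default `TRUE`)?
#' @return object of class `cross_basis` with fields `values` (n x df
#'   matrix), `spec`, and `valid_row_mask` (`FALSE` on padded rows).
#' @export
build_cross_basis <- function(x, spec, groups = NULL, pad = TRUE) {
  stopifnot(inherits(spec, "cross_basis_spec"))
  if (length(x) < spec$max_lag + 1L)
    stop("series shorter than max_lag + 1")
  lm <- lag_matrix(x, spec$max_lag, groups, pad)
  df_exp <- spec$exposure_spec$df
  df_lag <- spec$lag_spec$df
  n <- length(x)
  Blag <- ns_basis(0:spec$max_lag, spec$lag_spec)   # (L+1) x df_lag
  cb <- matrix(0, n, df_exp * df_lag)
  exp_idx <- rep(seq_len(df_exp), each = df_lag)
  for (l in 0:spec$max_lag) {
    E <- ns_basis(lm$values[, l + 1L], spec$exposure_spec)  # n x df_exp
    w <- rep(Blag[l + 1L, ], times = df_exp)                # df, exposure-major
    cb <- cb + E[, exp_idx, drop = FALSE] *
      matrix(w, n, df_exp * df_lag, byrow = TRUE)
  }
  colnames(cb) <- paste0("cb_e", exp_idx, "_l", rep(seq_len(df_lag), df_exp))
  structure(list(values = cb, spec = spec, valid_row_mask = !lm$padded),
            class = "cross_basis")
}

#' Lag-cumulation reduction map
#'
#' Returns the matrix M (df_exp*df_lag x df_exp) that collapses the full
#' cross-basis coefficient vector beta to the overall-cumulative
#' exposure-response coefficients theta = t(M) beta: M is the Kronecker lift
#' of s = column sums of the lag basis over integer lags 0..max_lag, so that
#' for a constant exposure history x the cumulative log-RR equals
#' b_exp(x) . theta. The reduced covariance is t(M) V M.
#'
#' @param spec a [cross_basis_spec()].
#' @return matrix of dimension `spec$df` x `df_exp`.
#' @export
lag_cumulation_map <- function(spec) {
  stopifnot(inherits(spec, "cross_basis_spec"))
  s <- colSums(ns_basis(0:spec$max_lag, spec$lag_spec))
  df_exp <- spec$exposure_spec$df
  df_lag <- spec$lag_spec$df
  M <- matrix(0, df_exp * df_lag, df_exp)
  for (j in seq_len(df_exp))
    M[(j - 1L) * df_lag + seq_len(df_lag), j] <- s
  M
}
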