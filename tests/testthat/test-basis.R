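# Independent truncated-power construction of the natural cubic spline
# space (ESL-style): {1, x, d_j(x) - d_{M-1}(x)} with
# d_j(x) = [(x - k_j)_+^3 - (x - k_M)_+^3] / (k_M - k_j) over all knots
# (boundary + internal). Used as the span oracle; never calls ns_basis.
truncated_power_natural <- function(x, internal, boundary) {
  k <- sort(c(boundary, internal))
  M <- length(k)
  d <- function(j) (pmax(x - k[j], 0)^3 - pmax(x - k[M], 0)^3) / (k[M] - k[j])
  cols <- cbind(1, x)
  for (j in seq_len(M - 2L)) cols <- cbind(cols, d(j) - d(M - 1L))
  cols
}

proj_residual <- function(target, onto) {
  fit <- stats::lm.fit(onto, target)
  max(abs(fit$residuals))
}

test_that("ns_basis has the natural-spline dimension and knot validation", {
  spec <- spline_spec(c(15, 25, 30), boundary = c(10, 35))
  expect_equal(ncol(ns_basis(seq(10, 35, 0.5), spec)), 4L)
  spec_i <- spline_spec(c(15, 25, 30), boundary = c(10, 35), intercept = TRUE)
  expect_equal(spec_i$df, 5L)
  expect_error(spline_spec(c(25, 15), c(10, 35)), "strictly increasing")
  expect_error(spline_spec(c(5, 25), c(10, 35)), "strictly inside")
})

test_that("ns_basis is exactly linear beyond the boundary knots", {
  spec <- spline_spec(c(15, 25, 30), boundary = c(10, 35))
  for (pts in list(c(36, 40, 44), c(2, 5, 8))) {
    B <- ns_basis(pts, spec)  # equally spaced -> zero second differences
    second_diff <- B[1, ] - 2 * B[2, ] + B[3, ]
    expect_lt(max(abs(second_diff)), 1e-10)
  }
})

test_that("ns_basis spans the truncated-power natural-spline space", {
  spec <- spline_spec(c(15, 25, 30), boundary = c(10, 35))
  x <- seq(8, 38, length.out = 400)
  B <- cbind(1, ns_basis(x, spec))
  O <- truncated_power_natural(x, c(15, 25, 30), c(10, 35))
  expect_equal(ncol(B), ncol(O))
  for (j in seq_len(ncol(O))) expect_lt(proj_residual(O[, j], B), 1e-8)
  for (j in seq_len(ncol(B))) expect_lt(proj_residual(B[, j], O), 1e-8)
})

test_that("ns_basis with an intercept reproduces straight lines", {
  spec <- spline_spec(c(2, 5), boundary = c(0, 10), intercept = TRUE)
  x <- seq(-1, 11, length.out = 200)
  target <- 3 - 0.7 * x
  expect_lt(proj_residual(target, ns_basis(x, spec)), 1e-8)
})

test_that("ns_basis propagates NA markers and rejects NaN/Inf", {
  spec <- spline_spec(c(2, 5), boundary = c(0, 10))
  B <- ns_basis(c(1, NA, 3), spec)
  expect_true(all(is.na(B[2, ])))
  expect_true(all(is.finite(B[c(1, 3), ])))
  expect_error(ns_basis(c(1, Inf), spec), "indices: 2")
  expect_error(ns_basis(c(NaN, 1), spec), "indices: 1")
})

test_that("log lag knots follow the closed form", {
  expect_equal(log_lag_knots(10, 2), c(10^(1 / 3), 10^(2 / 3)))
  expect_equal(log_lag_knots(10, 1), sqrt(10))
  # log-spacing: log of knots is an arithmetic sequence including endpoints
  k <- log_lag_knots(30, 4)
  steps <- diff(log(c(1, k, 30)))
  expect_equal(steps, rep(steps[1], 5))
})

test_that("cross-basis rows are constant for a constant series", {
  spec <- cross_basis_spec(toy_exposure_spec(),
                           spline_spec(log_lag_knots(10, 2), c(0, 10),
                                       intercept = TRUE), 10)
  cb <- build_cross_basis(rep(22, 40), spec)
  expect_equal(max(apply(cb$values, 2, function(v) diff(range(v)))), 0)
})

test_that("cross-basis dimensions follow df_exp x df_lag", {
  exposure <- toy_exposure_spec()                       # df 4
  lag3 <- spline_spec(log_lag_knots(3, 1), c(0, 3), intercept = TRUE)  # df 3
  spec <- cross_basis_spec(exposure, lag3, 3)
  cb <- build_cross_basis(rnorm(30, 22, 4), spec)
  expect_equal(dim(cb$values), c(30L, 12L))
  expect_error(build_cross_basis(rnorm(3), spec), "shorter")
})

test_that("cross-basis matches an explicit double-loop oracle", {
  set.seed(42)
  x <- rnorm(50, 22, 5)
  exposure <- toy_exposure_spec()
  lag <- spline_spec(log_lag_knots(3, 1), c(0, 3), intercept = TRUE)
  spec <- cross_basis_spec(exposure, lag, 3)
  cb <- build_cross_basis(x, spec)

  Bexp <- ns_basis(x, exposure)
  Blag <- ns_basis(0:3, lag)
  oracle <- matrix(0, 50, spec$df)
  for (t in 1:50) {
    for (j in 1:4) for (k in 1:3) {
      acc <- 0
      for (l in 0:3) {
        xl <- x[max(t - l, 1)]  # padding repeats the first value
        acc <- acc + ns_basis(xl, exposure)[1, j] * Blag[l + 1, k]
      }
      oracle[t, (j - 1) * 3 + k] <- acc
    }
  }
  expect_lt(max(abs(cb$values - oracle)), 1e-12)
})

test_that("season blocks reset the lag window and are flagged", {
  x <- c(1:6, 101:106)
  groups <- rep(1:2, each = 6)
  lag <- spline_spec(log_lag_knots(3, 1), c(0, 3), intercept = TRUE)
  spec <- cross_basis_spec(spline_spec(50, c(0, 110)), lag, 3)
  cb <- build_cross_basis(x, spec, groups = groups)
  expect_equal(cb$valid_row_mask, rep(c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE), 2))
  # row 7 (start of block 2) must not see block-1 values: identical to a
  # constant-history row at x = 101
  cb_const <- build_cross_basis(rep(101, 10), spec)
  expect_equal(unname(cb$values[7, ]), unname(cb_const$values[1, ]))
  # pad = FALSE leaves season-start rows NA
  cb_nopad <- build_cross_basis(x, spec, groups = groups, pad = FALSE)
  expect_true(all(is.na(cb_nopad$values[7:9, ])))
  expect_true(all(is.finite(cb_nopad$values[10:12, ])))
})

test_that("lag cumulation reproduces constant-history prediction", {
  set.seed(7)
  exposure <- toy_exposure_spec()
  lag <- spline_spec(log_lag_knots(10, 2), c(0, 10), intercept = TRUE)
  spec <- cross_basis_spec(exposure, lag, 10)
  M <- lag_cumulation_map(spec)
  expect_equal(dim(M), c(16L, 4L))
  beta <- rnorm(16)
  theta <- drop(crossprod(M, beta))
  for (x0 in c(12, 21, 29, 34)) {
    row <- build_cross_basis(rep(x0, 15), spec)$values[15, ]
    expect_equal(drop(row %*% beta),
                 drop(ns_basis(x0, exposure) %*% theta), tolerance = 1e-12)
  }
})

test_that("reduced covariance is a PSD congruence transform", {
  set.seed(8)
  spec <- cross_basis_spec(toy_exposure_spec(),
                           spline_spec(log_lag_knots(10, 2), c(0, 10),
                                       intercept = TRUE), 10)
  M <- lag_cumulation_map(spec)
  A <- matrix(rnorm(16 * 16), 16)
  V <- crossprod(A)
  Vr <- crossprod(M, V %*% M)
  expect_equal(Vr, t(Vr))
  expect_true(all(eigen(Vr, symmetric = TRUE)$values > -1e-10))
})

test_that("cross-basis prediction is translation-equivariant", {
  set.seed(9)
  x <- rnorm(60, 22, 4)
  shift <- 7.3
  spec1 <- cross_basis_spec(toy_exposure_spec(),
                            spline_spec(log_lag_knots(5, 1), c(0, 5),
                                        intercept = TRUE), 5)
  spec2 <- cross_basis_spec(
    spline_spec(spec1$exposure_spec$knots + shift,
                spec1$exposure_spec$boundary + shift),
    spec1$lag_spec, 5)
  cb1 <- build_cross_basis(x, spec1)
  cb2 <- build_cross_basis(x + shift, spec2)
  expect_equal(cb1$values, cb2$values, tolerance = 1e-10)
})
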