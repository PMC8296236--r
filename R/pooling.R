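# Symmetrize and clip a covariance estimate to the PSD cone.
psd_clip <- function(A) {
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  clipped <- any(e$values < 0)
  vals <- pmax(e$values, 0)
  list(mat = e$vectors %*% (vals * t(e$vectors)), clipped = clipped)
}

#' Multivariate random-effects meta-analysis of reduced curves
#'
#' Second stage of the two-stage design: city-level lag-cumulated
#' exposure-response coefficient vectors theta_i with within-city
#' covariances V_i are pooled under the model
#' theta_i ~ N(mu, V_i + Psi). The between-city covariance Psi is estimated
#' by the multivariate method of moments (the matrix generalization of
#' DerSimonian-Laird):
#' Psi = (S - (1 - 1/k) sum(V_i)) / (k - 1), with S the centred
#' cross-product of the theta_i, eigenvalue-clipped to positive
#' semidefinite. The pooled mean is then the GLS estimate
#' mu = (sum W_i)^{-1} sum W_i theta_i with W_i = (V_i + Psi)^{-1}.
#'
#' All curves must share the identical exposure spline (common basis);
#' a single curve returns itself with Psi = 0.
#'
#' @param curves list of [reduce_fit()] `reduced_curve` objects.
#' @return object of class `pooled_curves`: `mu`, `vcov_mu`, `psi`,
#'   `psi_clipped` flag, `blups` (list per city: `theta`, `vcov`),
#'   `exposure_spec`, `curves`.
#' @export
meta_fit <- function(curves) {
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1), "reduced_curve")))
  q <- length(curves[[1]]$theta)
  if (!all(vapply(curves, function(cu) length(cu$theta), integer(1)) == q))
    stop("curves have mismatched coefficient dimensions")
  spec0 <- curves[[1]]$exposure_spec
  same <- vapply(curves, function(cu)
    isTRUE(all.equal(cu$exposure_spec, spec0)), logical(1))
  if (!all(same)) stop("all curves must share the same exposure spline spec")

  k <- length(curves)
  th <- do.call(rbind, lapply(curves, function(cu) cu$theta))   # k x q
  Vs <- lapply(curves, function(cu) cu$vcov)

  if (k == 1L) {
    psi <- matrix(0, q, q)
    mu <- drop(th)
    vcov_mu <- Vs[[1]]
    clipped <- FALSE
  } else {
    thbar <- colMeans(th)
    S <- crossprod(sweep(th, 2, thbar))
    sumV <- Reduce(`+`, Vs)
    res <- psd_clip((S - (1 - 1 / k) * sumV) / (k - 1))
    psi <- res$mat
    clipped <- res$clipped
    Ws <- lapply(Vs, function(V) solve(V + psi))
    Wsum <- Reduce(`+`, Ws)
    vcov_mu <- solve(Wsum)
    mu <- drop(vcov_mu %*% Reduce(`+`, Map(function(W, i) W %*% th[i, ],
                                           Ws, seq_len(k))))
  }

  blups <- lapply(seq_len(k), function(i)
    blup_one(mu, vcov_mu, psi, curves[[i]]))
  names(blups) <- vapply(curves, function(cu) cu$city_id, character(1))

  structure(list(mu = mu, vcov_mu = vcov_mu, psi = psi,
                 psi_clipped = clipped, blups = blups,
                 exposure_spec = spec0, curves = curves),
            class = "pooled_curves")
}

blup_one <- function(mu, vcov_mu, psi, curve) {
  A <- psi %*% solve(curve$vcov + psi)          # shrinkage toward mu
  theta <- drop(mu + A %*% (curve$theta - mu))
  B <- diag(length(mu)) - A
  vcov <- psi - A %*% psi + B %*% vcov_mu %*% t(B)
  vcov <- (vcov + t(vcov)) / 2
  structure(list(theta = theta, vcov = vcov,
                 exposure_spec = curve$exposure_spec,
                 city_id = curve$city_id, metric = curve$metric),
            class = "reduced_curve")
}

#' Best linear unbiased prediction of a city curve
#'
#' Shrinks a city's first-stage curve toward the pooled mean:
#' BLUP = mu + Psi (V_i + Psi)^{-1} (theta_i - mu). With Psi = 0 the BLUP
#' collapses to the pooled mean; as V_i vanishes it returns the city's own
#' estimate.
#'
#' @param pooled a [meta_fit()] result.
#' @param curve a `reduced_curve` that entered the meta-analysis.
#' @return a `reduced_curve` holding the BLUP coefficients and covariance.
#' @export
blup <- function(pooled, curve) {
  stopifnot(inherits(pooled, "pooled_curves"), inherits(curve, "reduced_curve"))
  blup_one(pooled$mu, pooled$vcov_mu, pooled$psi, curve)
}
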