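#' Matern covariance parameters
#'
#' Bundles the hyperparameters of a stationary Matern covariance
#' \deqn{C(d) = \frac{\sigma^2}{2^{\nu-1}\Gamma(\nu)} (\kappa d)^\nu
#'   K_\nu(\kappa d),}
#' where \eqn{K_\nu} is the modified Bessel function of the second kind.
#' The practical range \eqn{\rho = \sqrt{8\nu}/\kappa} is the distance at
#' which the correlation has dropped to roughly 0.1; either `kappa` or
#' `rho` may be supplied and the other is derived.
#'
#' @param sigma2 Marginal variance, > 0.
#' @param nu Smoothness, > 0. Defaults to 1, the usual choice for areal
#'   analyses at tract scale.
#' @param kappa Inverse-scale parameter, > 0, units 1/metre. Exactly one of
#'   `kappa` and `rho` must be given.
#' @param rho Practical range in metres, > 0.
#'
#' @return An object of class `matern_params`: a list with elements
#'   `sigma2`, `nu`, `kappa`, `rho`.
#' @examples
#' p <- matern_params(sigma2 = 1, nu = 1, rho = 3000)
#' p$kappa * p$rho   # sqrt(8 * nu)
#' @export
matern_params <- function(sigma2 = 1, nu = 1, kappa = NULL, rho = NULL) {
  check_positive(sigma2, "sigma2")
  check_positive(nu, "nu")
  if (is.null(kappa) && is.null(rho)) {
    stop_invalid("Supply one of `kappa` or `rho`.")
  }
  if (!is.null(kappa) && !is.null(rho)) {
    stop_invalid("Supply only one of `kappa` and `rho`, not both.")
  }
  if (is.null(kappa)) {
    check_positive(rho, "rho")
    kappa <- sqrt(8 * nu) / rho
  } else {
    check_positive(kappa, "kappa")
    rho <- range_from_kappa(nu, kappa)
  }
  structure(
    list(sigma2 = sigma2, nu = nu, kappa = kappa, rho = rho),
    class = "matern_params"
  )
}

#' @export
print.matern_params <- function(x, ...) {
  cat(sprintf(
    "Matern covariance: sigma2 = %g, nu = %g, kappa = %g (range rho = %g m)\n",
    x$sigma2, x$nu, x$kappa, x$rho
  ))
  invisible(x)
}

#' Practical range of a Matern covariance
#'
#' Evaluates \eqn{\rho = \sqrt{8\nu}/\kappa}, the distance at which the
#' Matern correlation is close to 0.1.
#'
#' @param nu Smoothness, > 0.
#' @param kappa Inverse scale, > 0.
#' @return The range `rho`, in the units of `1/kappa`.
#' @examples
#' range_from_kappa(nu = 1, kappa = 2)  # sqrt(8)/2
#' @export
range_from_kappa <- function(nu, kappa) {
  check_positive(nu, "nu")
  check_positive(kappa, "kappa")
  sqrt(8 * nu) / kappa
}

#' Matern covariance function
#'
#' Evaluates the Matern covariance at one or more distances.  At distance
#' zero the limit value `sigma2` is returned exactly.
#'
#' @param distance Numeric vector of distances, >= 0.
#' @param params A [matern_params()] object.
#' @return Covariance values, same length as `distance`.
#' @examples
#' p <- matern_params(sigma2 = 1, nu = 0.5, kappa = 2)
#' matern_covariance(1, p)   # exp(-2), the exponential special case
#' @export
matern_covariance <- function(distance, params) {
  stopifnot(inherits(params, "matern_params"))
  if (!is.numeric(distance) || any(!is.finite(distance)) || any(distance < 0)) {
    stop_invalid("`distance` must be finite and non-negative.")
  }
  u <- params$kappa * distance
  out <- rep(params$sigma2, length(distance))
  pos <- u > 0
  if (any(pos)) {
    up <- u[pos]
    nu <- params$nu
    # log-scale evaluation keeps the prefactor stable for large nu
    lg <- nu * log(up) + log(besselK(up, nu)) - (nu - 1) * log(2) - lgamma(nu)
    out[pos] <- params$sigma2 * exp(lg)
  }
  out
}

#' Matern covariance matrix over point locations
#'
#' Builds the dense covariance matrix of a Matern field evaluated at a set
#' of planar locations (projected coordinates in metres), with a small
#' diagonal jitter so a Cholesky factorisation succeeds even for nearly
#' coincident points.
#'
#' @param centroids Two-column numeric matrix (or data frame with columns
#'   `x`, `y`) of point coordinates.
#' @param params A [matern_params()] object.
#' @param jitter Diagonal jitter; defaults to `1e-8 * sigma2`.
#' @return A symmetric positive-definite matrix with `sigma2 + jitter` on
#'   the diagonal.
#' @export
covariance_matrix <- function(centroids, params, jitter = NULL) {
  xy <- as_centroid_matrix(centroids)
  stopifnot(inherits(params, "matern_params"))
  jitter <- jitter %||% (1e-8 * params$sigma2)
  check_nonneg(jitter, "jitter")
  d <- as.matrix(stats::dist(xy))
  sig <- matern_covariance(as.vector(d), params)
  sig <- matrix(sig, nrow(xy), nrow(xy))
  diag(sig) <- params$sigma2 + jitter
  sig
}

# Cholesky with jitter escalation: 3 retries, x10 each.  Returns the lower
# triangular factor.
chol_with_jitter <- function(sigma, base_jitter) {
  for (k in 0:3) {
    mat <- sigma
    if (k > 0) diag(mat) <- diag(mat) + base_jitter * (10^k - 1)
    ch <- tryCatch(chol(mat), error = function(e) NULL)
    if (!is.null(ch)) return(t(ch))
  }
  abort(
    paste0(
      "Covariance matrix is not positive definite even after jitter ",
      "escalation (up to ", format(base_jitter * 1000), " on the diagonal); ",
      "check for duplicated centroids or an extreme range parameter."
    ),
    class = "hurdlemap_numerical_error"
  )
}

as_centroid_matrix <- function(centroids) {
  if (is.data.frame(centroids)) {
    if (!all(c("x", "y") %in% names(centroids))) {
      stop_invalid("`centroids` data frame needs columns `x` and `y`.")
    }
    centroids <- cbind(centroids$x, centroids$y)
  }
  xy <- as.matrix(centroids)
  if (ncol(xy) != 2 || nrow(xy) < 1 || any(!is.finite(xy))) {
    stop_invalid("`centroids` must be a finite n x 2 coordinate matrix.")
  }
  xy
}

#' Sample a zero-mean Matern Gaussian field at point locations
#'
#' Draws one realisation of a zero-mean multivariate normal with Matern
#' covariance over the given locations, via Cholesky factorisation.
#'
#' @inheritParams covariance_matrix
#' @param seed Integer seed; the draw is deterministic given `(inputs, seed)`.
#' @return Numeric vector of field values, one per location.
#' @export
sample_field <- function(centroids, params, seed, jitter = NULL) {
  xy <- as_centroid_matrix(centroids)
  sigma <- covariance_matrix(xy, params, jitter)
  ll <- chol_with_jitter(sigma, jitter %||% (1e-8 * params$sigma2))
  z <- with_seed(seed, rnorm(nrow(xy)))
  as.vector(ll %*% z)
}
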